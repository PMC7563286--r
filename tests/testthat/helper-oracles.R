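# Independent oracles used across tests. These deliberately do not share
# code with the package internals.

# Generic LP max c'v s.t. S v = 0, lb <= v <= ub, solved with pracma's
# simplex after shifting x = v - lb >= 0 (pracma::linprog assumes x >= 0).
lp_oracle_objective <- function(model, bounds = NULL) {
  S <- as.matrix(proflux::stoichiometric_matrix(model))
  obj <- unname(proflux::objective_coefficients(model))
  if (is.null(bounds)) bounds <- proflux::default_bounds(model)
  ids <- colnames(S)
  idx <- match(ids, bounds$reaction_id)
  lb <- bounds$lower_bound[idx]; ub <- bounds$upper_bound[idx]
  n <- length(obj)
  res <- tryCatch(
    pracma::linprog(cc = obj, A = diag(n), b = ub - lb,
                    Aeq = S, beq = as.numeric(-S %*% lb),
                    maxiter = 10000, maximize = TRUE),
    error = function(e) NULL)
  if (is.null(res) || res$errno != 1) return(NA_real_)
  sum(obj * (res$x + lb))
}

# Brute-force recursive GPR evaluator: plain min/max recursion with the
# "unbounded" missing-gene convention (NA = unmeasured; OR drops NA
# branches, AND propagates NA).
gpr_oracle_eval <- function(node, levels) {
  if (node$kind == "gene") {
    if (node$gene %in% names(levels)) return(unname(levels[[node$gene]]))
    return(NA_real_)
  }
  vals <- sapply(node$children, gpr_oracle_eval, levels = levels)
  if (node$kind == "or") {
    vals <- vals[!is.na(vals)]
    return(if (length(vals) == 0) NA_real_ else max(vals))
  }
  if (any(is.na(vals))) return(NA_real_)
  min(vals)
}

# Enumerate all GPR tree shapes of depth <= 3 with binary operator nodes
# over a gene alphabet (leaves range over all genes).
enumerate_gpr_trees <- function(genes) {
  leaf <- function(g) structure(list(kind = "gene", gene = g),
                                class = "gpr_expression")
  node <- function(kind, a, b) structure(
    list(kind = kind, children = list(a, b)), class = "gpr_expression")
  d1 <- lapply(genes, leaf)
  d2 <- list()
  for (op in c("and", "or"))
    for (a in d1) for (b in d1)
      d2[[length(d2) + 1]] <- node(op, a, b)
  d12 <- c(d1, d2)
  d3 <- list()
  for (op in c("and", "or"))
    for (a in d12) for (b in d12)
      d3[[length(d3) + 1]] <- node(op, a, b)
  c(d1, d2, d3)
}

# Hand-coded Welch two-sample t-test p-value (reference for select_de).
welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(t), df)
}

# Hand-coded Pearson correlation.
pearson_oracle <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# A hand-written 3-reaction chain (uptake -> conversion -> biomass) whose
# LP is solved on paper: Z* = min of the three upper bounds.
hand_chain_model <- function(cap_ex = 10, cap_r = 20, cap_bio = 30) {
  proflux::metabolic_model(
    data.frame(id = c("A", "B"), name = NA, compartment = "c"),
    list(
      proflux::reaction("EX_A", c(A = 1), lower_bound = 0, upper_bound = cap_ex,
                        categories = "exchange"),
      proflux::reaction("AB", c(A = -1, B = 1), upper_bound = cap_r),
      proflux::reaction("BIO", c(B = -1), upper_bound = cap_bio,
                        objective_coefficient = 1)),
    "BIO")
}

# Random toy-network spec for the solver equivalence sweeps (<= 12
# reactions: 1 exchange + chain + 2 per detour + 3 per cycle + biomass).
random_toy_spec <- function(seed) {
  set.seed(seed)
  k <- sample(2:5, 1)
  spec <- proflux::toy_model_spec(
    n_linear_chain = k,
    n_parallel_paths = sample(0:2, 1),
    n_cycles = sample(0:1, 1),
    exchange_cap = round(runif(1, 1, 50), 3),
    seed = seed)
  spec
}

# Random bounds for a model: tighten defaults by random expression-like
# levels on a random subset of reactions.
random_levels <- function(model, seed) {
  set.seed(seed)
  g <- model$genes
  lv <- round(runif(length(g), 0, 30), 3)
  names(lv) <- g
  keep <- runif(length(g)) < 0.8
  lv[keep]
}
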