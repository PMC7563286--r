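#' Flux distributions
#'
#' Result container for the LP stages: per-reaction fluxes `v`, the
#' objective value `Z = C'v`, the solver status and the stage that
#' produced it (`"fba"` for plain biomass maximization, `"pfba"` after
#' total-absolute-flux minimization).
#'
#' @param fluxes Named numeric vector (reaction id -> flux).
#' @param objective_value `C'v` at the solution.
#' @param status One of `"optimal"`, `"infeasible"`, `"unbounded"`.
#' @param stage `"fba"` or `"pfba"`.
#' @param total_flux For pFBA solutions, the minimized sum of absolute
#'   fluxes.
#' @return An object of class `"flux_distribution"`.
#' @export
flux_distribution <- function(fluxes, objective_value, status, stage,
                              total_flux = NA_real_) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status, stage = stage, total_flux = total_flux),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> stage=%s status=%s Z=%.6g (%d reactions)\n",
              x$stage, x$status, x$objective_value, length(x$fluxes)))
  invisible(x)
}

#' @export
as.data.frame.flux_distribution <- function(x, ...) {
  data.frame(reaction_id = names(x$fluxes), flux = unname(x$fluxes),
             row.names = NULL)
}

## Generic bounded LP over the simplex method in 'boot':
##   optimize  obj'v   s.t.  Aeq v = beq,  Age v >= bge,  lb <= v <= ub.
## Variables are shifted to x = v - lb >= 0 and rows with negative rhs are
## re-oriented, since the simplex routine requires nonnegative variables
## and right-hand sides. All bounds must be finite (models carry finite
## defaults, conventionally +-1000).
solve_lp <- function(obj, Aeq, beq, lb, ub, Age = NULL, bge = NULL,
                     maximize = TRUE, eps = 1e-10) {
  n <- length(obj)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("LP requires finite variable bounds")
  if (any(lb > ub)) stop("LP bounds with lb > ub")

  # Variables pinned by equal bounds (e.g. knockouts) are substituted out
  # before the simplex call; zero-width columns trip its degeneracy
  # handling.
  Aeq <- matrix(as.numeric(as.matrix(Aeq)), ncol = n)
  fixed <- (ub - lb) == 0
  if (any(fixed)) {
    free <- !fixed
    beq_r <- beq - as.numeric(Aeq[, fixed, drop = FALSE] %*% lb[fixed])
    if (!is.null(Age)) {
      Age <- matrix(Age, ncol = n)
      bge <- bge - as.numeric(Age[, fixed, drop = FALSE] %*% lb[fixed])
      Age <- Age[, free, drop = FALSE]
    }
    if (!any(free)) {  # fully pinned: feasibility check only
      feas <- max(abs(beq_r)) <= 1e-9 &&
        (is.null(Age) || all(bge <= 1e-9))
      if (!feas)
        return(list(status = "infeasible", v = rep(NA_real_, n),
                    value = NA_real_))
      return(list(status = "optimal", v = lb, value = sum(obj * lb)))
    }
    sub <- solve_lp(obj[free], Aeq[, free, drop = FALSE], beq_r,
                    lb[free], ub[free], Age = Age, bge = bge,
                    maximize = maximize, eps = eps)
    v <- lb
    v[free] <- sub$v
    if (sub$status != "optimal") v <- rep(NA_real_, n)
    return(list(status = sub$status, v = v,
                value = if (sub$status == "optimal") sum(obj * v) else NA_real_))
  }

  # Standard form over z = (x, s, t) >= 0:
  #   Aeq x            = beq - Aeq lb
  #   x + s            = ub - lb        (variable upper bounds)
  #   Age x        - t = bge - Age lb   (optional >= side constraints)
  w <- ub - lb
  m1 <- nrow(Aeq)
  mge <- if (is.null(Age)) 0L else nrow(matrix(Age, ncol = n))
  N <- n + n + mge
  A <- matrix(0, m1 + n + mge, N)
  A[seq_len(m1), seq_len(n)] <- Aeq
  A[m1 + seq_len(n), seq_len(n)] <- diag(n)
  A[m1 + seq_len(n), n + seq_len(n)] <- diag(n)
  b <- c(as.numeric(beq - Aeq %*% lb), w)
  if (mge > 0) {
    Age <- matrix(Age, ncol = n)
    A[m1 + n + seq_len(mge), seq_len(n)] <- Age
    A[m1 + n + seq_len(mge), 2 * n + seq_len(mge)] <- -diag(mge)
    b <- c(b, as.numeric(bge - Age %*% lb))
  }
  cc <- numeric(N)
  cc[seq_len(n)] <- if (maximize) -obj else obj
  sol <- simplex_two_phase(A, b, cc, eps = eps)
  if (sol$status == "infeasible")
    return(list(status = "infeasible", v = rep(NA_real_, n), value = NA_real_))
  if (sol$status != "optimal")
    stop("LP solver failed: ", sol$status)
  v <- sol$z[seq_len(n)] + lb
  list(status = "optimal", v = v, value = sum(obj * v))
}

# Dense two-phase primal simplex with Bland's anti-cycling rule:
#   min cc'z  s.t.  A z = b, z >= 0.
# Bland's rule makes termination unconditional; the deterministic pivot
# order makes repeated solves bitwise reproducible. Problem sizes here are
# small (tens of variables), so the full-tableau form is adequate.
simplex_two_phase <- function(A, b, cc, eps = 1e-9) {
  m <- nrow(A); N <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  # initial basis from ready-made unit columns, artificials elsewhere
  basis <- integer(m)
  for (j in seq_len(N)) {
    nz <- which(A[, j] != 0)
    if (length(nz) == 1 && A[nz, j] == 1 && basis[nz] == 0) basis[nz] <- j
  }
  need_art <- which(basis == 0)
  n_art <- length(need_art)
  if (n_art > 0) {
    Art <- matrix(0, m, n_art)
    Art[cbind(need_art, seq_len(n_art))] <- 1
    A <- cbind(A, Art)
    basis[need_art] <- N + seq_len(n_art)
  }
  Ntot <- ncol(A)
  T <- cbind(A, b)
  # reduce rows so the basis columns form an identity
  for (i in seq_len(m)) {
    piv <- T[i, basis[i]]
    if (abs(piv - 1) > 0) T[i, ] <- T[i, ] / piv
    for (k in seq_len(m)[-i])
      if (T[k, basis[i]] != 0) T[k, ] <- T[k, ] - T[k, basis[i]] * T[i, ]
  }

  run <- function(T, basis, cost, allowed) {
    for (it in seq_len(50000)) {
      red <- cost - as.numeric(cost[basis] %*% T[, seq_len(Ntot), drop = FALSE])
      red[!allowed] <- 0
      ent <- which(red < -eps)
      if (length(ent) == 0) return(list(T = T, basis = basis))
      j <- ent[1]                                   # Bland: smallest index
      col <- T[, j]
      pos <- which(col > eps)
      if (length(pos) == 0) return(list(T = T, basis = basis,
                                        unbounded = TRUE))
      ratio <- T[pos, Ntot + 1] / col[pos]
      cand <- pos[ratio <= min(ratio) + eps]
      i <- cand[which.min(basis[cand])]             # Bland on ties
      T[i, ] <- T[i, ] / T[i, j]
      upd <- which(abs(T[, j]) > 0 & seq_len(m) != i)
      if (length(upd) > 0)
        T[upd, ] <- T[upd, ] - outer(T[upd, j], T[i, ])
      basis[i] <- j
    }
    stop("simplex iteration limit reached")
  }

  if (n_art > 0) {
    cost1 <- c(rep(0, N), rep(1, n_art))
    res <- run(T, basis, cost1, allowed = rep(TRUE, Ntot))
    T <- res$T; basis <- res$basis
    if (sum(cost1[basis] * T[, Ntot + 1]) > 1e-7)
      return(list(status = "infeasible"))
    # drive leftover zero-level artificials out of the basis when possible
    for (i in which(basis > N)) {
      j <- which(abs(T[i, seq_len(N)]) > eps)[1]
      if (!is.na(j)) {
        T[i, ] <- T[i, ] / T[i, j]
        upd <- which(abs(T[, j]) > 0 & seq_len(m) != i)
        if (length(upd) > 0)
          T[upd, ] <- T[upd, ] - outer(T[upd, j], T[i, ])
        basis[i] <- j
      }
    }
  }

  cost2 <- c(cc, rep(0, n_art))
  allowed <- c(rep(TRUE, N), rep(FALSE, n_art))
  res <- run(T, basis, cost2, allowed)
  if (isTRUE(res$unbounded)) return(list(status = "unbounded"))
  T <- res$T; basis <- res$basis
  z <- numeric(N)
  keep <- basis <= N
  z[basis[keep]] <- T[keep, Ntot + 1]
  list(status = "optimal", z = z, value = sum(cc * z))
}

model_lp_parts <- function(model, bounds) {
  rids <- reaction_ids(model)
  idx <- bounds_index(bounds, rids)
  list(S = as.matrix(stoichiometric_matrix(model)),
       obj = unname(objective_coefficients(model)),
       lb = bounds$lower_bound[idx],
       ub = bounds$upper_bound[idx],
       rids = rids)
}

#' Maximize the biomass objective (FBA)
#'
#' Solves the flux balance analysis linear program
#' \deqn{\max_v\ C'v \quad \mathrm{s.t.}\ Sv = 0,\ L \le v \le U,}
#' where `S` is the stoichiometric matrix, `C'` the objective coefficient
#' row (normally the biomass reaction) and `L`, `U` the bounds supplied.
#'
#' @param model A validated [metabolic_model()].
#' @param bounds A [bound_set()]; defaults to the model's own bounds.
#' @return A [flux_distribution()] with `stage = "fba"`. Infeasibility is
#'   reported via `status`, never silently.
#' @export
solve_fba <- function(model, bounds = default_bounds(model)) {
  assert_valid_model(model)
  p <- model_lp_parts(model, bounds)
  sol <- solve_lp(p$obj, Aeq = p$S, beq = rep(0, nrow(p$S)),
                  lb = p$lb, ub = p$ub, maximize = TRUE)
  fl <- sol$v; names(fl) <- p$rids
  flux_distribution(fl, sol$value, sol$status, "fba")
}

#' Minimize total absolute flux at (near-)optimal biomass (pFBA)
#'
#' Among the alternative FBA optima, selects a parsimonious flux
#' distribution by solving
#' \deqn{\min_v \sum_i |v_i| \quad \mathrm{s.t.}\ Sv = 0,\ L \le v \le U,\
#' C'v \ge \gamma Z^{opt},}
#' reflecting the assumption that the cell meets its objective with the
#' least enzymatic resource allocation. The absolute values are handled by
#' the standard flux split \eqn{v = v^+ - v^-} with \eqn{v^+, v^- \ge 0},
#' giving a plain LP. The biomass constraint is relaxed by a relative
#' `1e-9` to absorb solver round-off. L1 minimality does not strictly
#' guarantee uniqueness of `v`; the solver is deterministic (fixed
#' variable order, single-threaded), so repeated runs agree.
#'
#' @inheritParams solve_fba
#' @param z_opt Objective value from a prior optimal [solve_fba()].
#' @param gamma Fraction of `z_opt` that must be retained, in (0, 1];
#'   default 1.
#' @param exclude Reaction ids whose |flux| is left out of the minimized
#'   sum (e.g. exchange reactions); empty by default, so the sum runs over
#'   all reactions.
#' @return A [flux_distribution()] with `stage = "pfba"`;
#'   `objective_value` is the biomass `C'v` of the parsimonious solution
#'   and `total_flux` the minimized sum.
#' @export
minimize_total_flux <- function(model, bounds = default_bounds(model), z_opt,
                                gamma = 1.0, exclude = character()) {
  stopifnot(is.numeric(z_opt), length(z_opt) == 1, is.finite(z_opt))
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1)
    stop("gamma must be in (0, 1]")
  assert_valid_model(model)
  p <- model_lp_parts(model, bounds)
  n <- length(p$obj)
  keep <- !(p$rids %in% exclude)
  obj2 <- c(as.numeric(keep), as.numeric(keep))        # sum(v+ + v-)
  Aeq2 <- cbind(p$S, -p$S)
  lb2 <- c(pmax(p$lb, 0), pmax(-p$ub, 0))
  ub2 <- c(pmax(p$ub, 0), pmax(-p$lb, 0))
  target <- gamma * z_opt - 1e-9 * max(1, abs(z_opt))
  Age2 <- matrix(c(p$obj, -p$obj), nrow = 1)
  sol <- solve_lp(obj2, Aeq = Aeq2, beq = rep(0, nrow(p$S)),
                  lb = lb2, ub = ub2, Age = Age2, bge = target,
                  maximize = FALSE)
  if (sol$status != "optimal") {
    fl <- rep(NA_real_, n); names(fl) <- p$rids
    return(flux_distribution(fl, NA_real_, sol$status, "pfba"))
  }
  v <- sol$v[seq_len(n)] - sol$v[n + seq_len(n)]
  names(v) <- p$rids
  flux_distribution(v, sum(p$obj * v), "optimal", "pfba",
                    total_flux = sum(abs(v[keep])))
}

#' Run the full proteome-constrained simulation
#'
#' Composes the pipeline stages: expression bounds via [apply_eflux()],
#' optional in silico [knockout()] and [overexpress()] edits, biomass
#' maximization ([solve_fba()]) and parsimonious flux selection
#' ([minimize_total_flux()]).
#'
#' @inheritParams apply_eflux
#' @param knockouts Reaction ids to knock out (bounds to zero).
#' @param overexpressions Reaction ids to overexpress.
#' @param oe_factor Overexpression bound multiplier (default 2).
#' @param gamma,exclude Passed to [minimize_total_flux()].
#' @return A [flux_distribution()] with `stage = "pfba"` (or the failing
#'   stage's distribution if the LP is not optimal).
#' @export
simulate_fluxes <- function(model, levels, knockouts = character(),
                            overexpressions = character(), oe_factor = 2.0,
                            scale = 1.0,
                            missing_policy = c("unbounded", "zero", "ignore"),
                            cap_at_default = FALSE, gamma = 1.0,
                            exclude = character()) {
  missing_policy <- match.arg(missing_policy)
  b <- apply_eflux(model, levels, scale = scale,
                   missing_policy = missing_policy,
                   cap_at_default = cap_at_default)
  b <- knockout(b, knockouts)
  b <- overexpress(b, overexpressions, factor = oe_factor)
  fba <- solve_fba(model, b)
  if (fba$status != "optimal") return(fba)
  minimize_total_flux(model, b, z_opt = fba$objective_value, gamma = gamma,
                      exclude = exclude)
}

#' Export a flux distribution with its bounds to TSV
#'
#' @param fd A [flux_distribution()].
#' @param bounds The [bound_set()] used to produce it.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fluxes <- function(fd, bounds, path) {
  idx <- bounds_index(bounds, names(fd$fluxes))
  out <- data.frame(reaction_id = names(fd$fluxes),
                    flux = num17(unname(fd$fluxes)),
                    lb = num17(bounds$lower_bound[idx]),
                    ub = num17(bounds$upper_bound[idx]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
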