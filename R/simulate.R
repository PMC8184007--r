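#' Sample heterogeneous initial conditions for a simulated cell
#'
#' Draws the nucleation-site count, synapse fraction, autophagosome count
#' and free monomer pool from their empirical distributions (see
#' [InitDistributions-class]); negative draws are truncated at zero and
#' counts rounded to integers.
#'
#' @param dists an [InitDistributions-class].
#' @param wildType logical; `TRUE` (default) draws the monomer pool at the
#'   endogenous expression level (mean 108000), `FALSE` at the
#'   GFP-overexpressing level (mean 540000).
#' @param withAutophagosomes logical; `FALSE` initializes a degradation-free
#'   cell (growth-only studies).
#' @return list of class `SimCell`.
#' @export
sampleInitialConditions <- function(dists = InitDistributions(),
                                    wildType = TRUE,
                                    withAutophagosomes = TRUE) {
  nsite <- max(0L, as.integer(round(
    rgamma(1, shape = dists@siteShape, scale = dists@siteScale))))
  syn <- max(0, rnorm(1, dists@synapseMean, dists@synapseSd))
  nauto <- if (withAutophagosomes)
    max(0L, as.integer(round(
      rgamma(1, shape = dists@autoShape, scale = dists@autoScale)))) else 0L
  mm <- if (wildType) c(dists@monomerMean, dists@monomerSd) else
    c(dists@overexprMean, dists@overexprSd)
  nmono <- max(0L, as.integer(round(rnorm(1, mm[1], mm[2]))))
  newSimCell(nsite, syn, nmono, nauto)
}

#' Construct a simulated cell in its initial state
#'
#' @param n_sites number of inactive Carma1 nucleation sites.
#' @param synapse_fraction fraction of membrane in the immunological
#'   synapse.
#' @param n_monomers free Bcl10 monomer pool.
#' @param n_autophagosomes number of autophagosomes.
#' @return list of class `SimCell` (state vectors consumed by [stepCell()]
#'   and [runCell()]).
#' @export
newSimCell <- function(n_sites, synapse_fraction, n_monomers,
                       n_autophagosomes = 0L) {
  structure(list(
    site_status = rep(0L, n_sites),
    fil_len = integer(), fil_site = integer(), fil_grow = integer(),
    fil_consuming = integer(),
    auto_state = rep(0L, n_autophagosomes),
    auto_fil = rep(-1L, n_autophagosomes),
    auto_pos = rep(0L, n_autophagosomes),
    auto_mode = rep(0L, n_autophagosomes),
    free_monomers = as.numeric(n_monomers),
    degraded_monomers = 0,
    synapse_fraction = synapse_fraction), class = "SimCell")
}

#' @export
print.SimCell <- function(x, ...) {
  alive <- x$fil_len > 0
  cat(sprintf(
    "SimCell: %d sites (%d active), %d filaments (%d puncta-scale), free %g, degraded %g\n",
    length(x$site_status), sum(x$site_status != 0L), sum(alive),
    sum(alive & x$fil_len < 50), x$free_monomers, x$degraded_monomers))
  invisible(x)
}

.paramsList <- function(params, mode) {
  list(p_activate = params@pActivate, p_attach = params@pAttach,
       p_grow = params@pGrow, n_barrier = params@nBarrier,
       p_collide_carma = params@pCollideCarma,
       p_collide_bcl10 = params@pCollideBcl10,
       p_collide_auto = params@pCollideAuto,
       p_attach_auto = params@pAttachAuto,
       p_degrade = params@pDegrade, p_detach = params@pDetach,
       punctum_len = params@punctumLen, max_iter = params@maxIter,
       growth_law = match(params@growthLaw,
                          c("per_monomer", "mass_action", "per_site",
                            "hybrid")) - 1L,
       target_choice = match(params@targetChoice,
                             c("length", "uniform")) - 1L,
       mode = if (mode == "growth") 0L else 1L)
}

#' Advance a simulated cell by one synchronous iteration
#'
#' Applies, in order: (1) activation of inactive Carma1 sites with
#' probability `pCollideCarma * synapse_fraction * pActivate`; (2) monomer
#' attachment to each growth-enabled structure under the configured growth
#' law, with the pre-barrier probability `pAttach` below `nBarrier`
#' monomers and `pGrow` above; (3) autophagosome dynamics -- free
#' autophagosomes collide (`pCollideAuto`) with a length-weighted random
#' filament and attach (`pAttachAuto`) at a uniform monomer position;
#' attached autophagosomes degrade with `pDegrade` (end attachment removes
#' one monomer; interior attachment causes scission into a stable,
#' site-attached daughter and a consumed daughter) or otherwise detach with
#' `pDetach`. The integer monomer ledger (free + filamentous + degraded) is
#' asserted every iteration. Per-entity order is randomized within each
#' phase.
#'
#' @param cell a `SimCell`.
#' @param params a [SimParams-class].
#' @param mode `"growth"` or `"growth+degradation"` (affects only the
#'   termination rule in [runCell()]).
#' @return the updated `SimCell`.
#' @export
stepCell <- function(cell, params = SimParams(),
                     mode = c("growth+degradation", "growth")) {
  mode <- match.arg(mode)
  res <- run_cell_cpp(unclass(cell), .paramsList(params, mode), 1L, FALSE)
  structure(res$state, class = "SimCell")
}

#' Run one simulated cell to termination
#'
#' Growth-only mode runs until the free monomer pool reaches zero (capped
#' at `maxIter`); growth+degradation mode runs for `maxIter` iterations or
#' until both monomeric and filamentous Bcl10 reach zero, whichever comes
#' first. Puncta are filaments with `0 < length < punctumLen`.
#'
#' @param cell a `SimCell`.
#' @param params a [SimParams-class].
#' @param mode `"growth"` or `"growth+degradation"`.
#' @param record_trace logical; record the per-iteration trace matrix
#'   (columns: iter, free, filamentous, degraded, n_structures, n_puncta,
#'   mean_len, mean_len_filament, n_active_degradation).
#' @return list of class `SimTrace`: `state` (final `SimCell`), `trace`
#'   (matrix or NULL), `iterations`, `lengths` (final filament lengths),
#'   `n_puncta`, `mean_filament_length` (mean over non-punctate filaments).
#' @export
runCell <- function(cell, params = SimParams(),
                    mode = c("growth+degradation", "growth"),
                    record_trace = TRUE) {
  mode <- match.arg(mode)
  res <- run_cell_cpp(unclass(cell), .paramsList(params, mode), -1L,
                      record_trace)
  st <- res$state
  lens <- st$fil_len[st$fil_len > 0]
  npunc <- sum(lens < params@punctumLen)
  mfl <- if (any(lens >= params@punctumLen))
    mean(lens[lens >= params@punctumLen]) else NA_real_
  structure(list(state = structure(st, class = "SimCell"),
                 trace = if (record_trace) res$trace else NULL,
                 iterations = res$iterations,
                 lengths = lens, n_puncta = npunc,
                 mean_filament_length = mfl),
            class = "SimTrace")
}

#' Simulate a heterogeneous population of cells
#'
#' Simulates `n_trials` independent runs of each cell and pools the
#' resulting filament-length distributions per cell (the reported
#' distributions are cumulative over trials). The end-state correlation
#' `rho` is the Pearson product-moment correlation across cells between the
#' pooled puncta count and the pooled mean filament length (non-punctate
#' structures). When traces are recorded the population curves are
#' computed: `rho_t` (per-iteration correlation between per-cell punctate
#' fraction and mean filament length), the normalized mean filamentous
#' concentration, and per-cell `n_max` / `n_half` response-timing summaries.
#'
#' The same `cells` list should be passed across parameter configurations
#' so that parameter effects are compared on one heterogeneous population.
#'
#' @param cells list of `SimCell` objects (see
#'   [sampleInitialConditions()]); cells are re-initialized per trial from
#'   their stored initial conditions.
#' @param params a [SimParams-class].
#' @param n_trials trials per cell (default 10).
#' @param mode `"growth"` or `"growth+degradation"`.
#' @param record_curves logical; compute over-time population curves
#'   (requires the degradation mode's fixed iteration horizon).
#' @param punctate_measure `"structures"` (punctate fraction of structure
#'   count, default) or `"monomers"` for the over-time curves.
#' @return list of class `PopulationResult`: `rho` (end-state), `per_cell`
#'   data.frame (puncta, mean_len, n_sites, n_monomers), `lengths` (pooled
#'   per-cell length lists), and when curves are recorded `rho_t`,
#'   `concentration` (normalized to its max), `n_max`, `n_half`.
#' @export
runPopulation <- function(cells, params = SimParams(), n_trials = 10L,
                          mode = c("growth", "growth+degradation"),
                          record_curves = FALSE,
                          punctate_measure = c("structures", "monomers")) {
  mode <- match.arg(mode)
  punctate_measure <- match.arg(punctate_measure)
  ncell <- length(cells)
  stopifnot(ncell >= 1, n_trials >= 1)
  horizon <- params@maxIter
  puncta <- numeric(ncell); meanlen <- numeric(ncell)
  lengths <- vector("list", ncell)
  pf_mat <- ml_mat <- conc_mat <- NULL
  if (record_curves) {
    pf_mat <- matrix(NA_real_, ncell, horizon + 1)
    ml_mat <- matrix(NA_real_, ncell, horizon + 1)
    conc_mat <- matrix(0, ncell, horizon + 1)
  }
  nmax <- rep(NA_real_, ncell); nhalf <- rep(NA_real_, ncell)

  for (ci in seq_len(ncell)) {
    cell0 <- cells[[ci]]
    pooled <- integer()
    if (record_curves) {
      pf_acc <- matrix(0, n_trials, horizon + 1)
      ml_acc <- matrix(NA_real_, n_trials, horizon + 1)
      fc_acc <- matrix(0, n_trials, horizon + 1)
      nm_tr <- rep(NA_real_, n_trials); nh_tr <- rep(NA_real_, n_trials)
    }
    for (tr in seq_len(n_trials)) {
      fresh <- newSimCell(length(cell0$site_status), cell0$synapse_fraction,
                          cell0$free_monomers, length(cell0$auto_state))
      res <- runCell(fresh, params, mode, record_trace = record_curves)
      pooled <- c(pooled, res$lengths)
      if (record_curves) {
        trm <- res$trace
        ni <- nrow(trm)
        idx <- seq_len(min(ni, horizon + 1))
        fil <- trm[idx, "filamentous"]
        nstr <- trm[idx, "n_structures"]
        npv <- trm[idx, "n_puncta"]
        pf <- if (punctate_measure == "structures")
          ifelse(nstr > 0, npv / nstr, NA_real_) else {
            punc_mono <- fil - ifelse(is.na(trm[idx, "mean_len_filament"]), 0,
              trm[idx, "mean_len_filament"] * (nstr - npv))
            ifelse(fil > 0, pmax(0, punc_mono) / fil, NA_real_)
          }
        pf_acc[tr, idx] <- pf
        ml_acc[tr, idx] <- trm[idx, "mean_len"]
        fc_acc[tr, idx] <- fil
        if (ni < horizon + 1) {            # cell fully degraded: stays empty
          fc_acc[tr, (ni + 1):(horizon + 1)] <- 0
        }
        im <- which.max(fc_acc[tr, ])
        nm_tr[tr] <- im - 1
        later <- which(fc_acc[tr, ] <= fc_acc[tr, im] / 2)
        later <- later[later > im]
        nh_tr[tr] <- if (length(later)) later[1] - 1 else NA_real_
      }
    }
    puncta[ci] <- sum(pooled > 0 & pooled < params@punctumLen)
    big <- pooled[pooled >= params@punctumLen]
    meanlen[ci] <- if (length(big)) mean(big) else NA_real_
    lengths[[ci]] <- pooled
    if (record_curves) {
      pf_mat[ci, ] <- colMeans(pf_acc, na.rm = TRUE)
      ml_mat[ci, ] <- colMeans(ml_acc, na.rm = TRUE)
      conc_mat[ci, ] <- colMeans(fc_acc)
      nmax[ci] <- mean(nm_tr, na.rm = TRUE)
      nhalf[ci] <- if (all(is.na(nh_tr))) NA_real_ else mean(nh_tr, na.rm = TRUE)
    }
  }

  rho <- pearsonRho(puncta, meanlen)
  out <- list(rho = rho,
              per_cell = data.frame(
                puncta = puncta, mean_len = meanlen,
                n_sites = vapply(cells, function(c) length(c$site_status), 0L),
                n_monomers = vapply(cells, function(c) c$free_monomers, 0)),
              lengths = lengths)
  if (record_curves) {
    rho_t <- vapply(seq_len(horizon + 1), function(i)
      pearsonRho(pf_mat[, i], ml_mat[, i]), 0)
    mc <- colMeans(conc_mat)
    out$rho_t <- rho_t
    out$peak <- max(mc)            # unnormalized peak mean concentration
    out$concentration <- mc / max(mc)
    out$n_max <- nmax
    out$n_half <- nhalf
  }
  class(out) <- "PopulationResult"
  out
}

#' @export
print.PopulationResult <- function(x, ...) {
  cat(sprintf("PopulationResult: %d cells, end-state rho = %.3f\n",
              nrow(x$per_cell), x$rho))
  invisible(x)
}

#' Two-phase nucleation-limited growth distribution
#'
#' Probability that a filament has length `x` after `n` attempted
#' attachments when each pre-barrier attempt succeeds with `p_attach`, the
#' barrier is crossed at `L0` monomers, and each post-barrier attempt
#' succeeds with `p_grow`:
#' below the barrier the length is binomial,
#' `C(n, x) p_attach^x (1 - p_attach)^(n - x)`;
#' at or above it the probability convolves the negative-binomial waiting
#' time for the barrier crossing at iteration `i` with binomial
#' post-barrier growth over the remaining `n - i` attempts,
#' `sum_i C(i-1, L0-1) p_attach^L0 (1-p_attach)^(i-L0) *
#'  C(n-i, x-L0) p_grow^(x-L0) (1-p_grow)^((n-i)-(x-L0))`.
#' Computed in log space; the pmf sums to 1 to within 1e-9 for `n` up to a
#' few hundred.
#'
#' @param n number of attempted attachments (iterations).
#' @param x length (monomers); vectorized. `x > n` returns 0.
#' @param L0 nucleation-barrier size (>= 1).
#' @param p_attach,p_grow phase probabilities in [0, 1].
#' @return numeric vector of probabilities.
#' @export
growthPmf <- function(n, x, L0, p_attach, p_grow) {
  stopifnot(n >= 0, L0 >= 1, p_attach >= 0, p_attach <= 1,
            p_grow >= 0, p_grow <= 1)
  vapply(x, function(xi) {
    if (xi < 0 || xi > n) return(0)
    if (xi < L0) return(dbinom(xi, n, p_attach))
    imax <- n - (xi - L0)
    if (imax < L0) return(0)
    i <- L0:imax
    pre <- ifelse(i == L0, 0, (i - L0) * log1p(-p_attach))
    lt <- lchoose(i - 1, L0 - 1) + L0 * log(p_attach) + pre +
      dbinom(xi - L0, n - i, p_grow, log = TRUE)
    m <- max(lt)
    if (!is.finite(m)) return(0)
    exp(m) * sum(exp(lt - m))
  }, 0)
}
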