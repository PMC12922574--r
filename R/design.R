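#' Fisher information of the T2-IVIM model over a (b, TE) design
#'
#' Under additive Gaussian noise of SD `sigma`, the information matrix of
#' the T2-compensated forward model is
#' \deqn{F = \sigma^{-2} J^\top W J}
#' with `J` the Jacobian of [t2ivim_signal()] over the design points and
#' `W` a diagonal matrix of per-point averages. By default the parameter
#' set is (f, D, D*, T2_tissue, T2_fluid) with the scale fixed by
#' normalization (the simulation convention): the model is evaluated at
#' the constant scale that makes its b = 0 signal at `reference_te` equal
#' to 1, so `sigma` and the Jacobian live on the same normalized-signal
#' scale the simulator produces. `include_s0 = TRUE` instead appends a
#' free S0 (the in-vivo convention).
#'
#' @param state A [tissue_state()] (its T2 values and IVIM parameters are
#'   the linearization point; T1 terms do not enter the T2-only model).
#' @param b_values,te_values The design points (all b x TE combinations).
#' @param sigma Gaussian noise SD on the normalized signal scale, `> 0`.
#' @param averages Optional per-b averages (diagonal weights).
#' @param include_s0 Append S0 to the parameter set.
#' @param reference_te Normalization anchor in ms; default the smallest
#'   design TE.
#' @return The information matrix with named dimensions; attribute
#'   `"condition"` carries its condition number.
#' @export
fisher_information <- function(state, b_values, te_values, sigma,
                               averages = NULL, include_s0 = FALSE,
                               reference_te = min(te_values)) {
  stopifnot(inherits(state, "tissue_state"), sigma > 0)
  p <- c(f = state$ivim$f, D = state$ivim$D, D_star = state$ivim$D_star,
         T2_tissue = state$relax$T2_tissue, T2_fluid = state$relax$T2_fluid)
  # normalization-fixed scale: unit signal at (b = 0, reference_te)
  s0_fix <- 1 / .model_eval(p, 0, reference_te)
  p <- c(p, S0 = s0_fix)
  keep <- c("f", "D", "D_star", "T2_tissue", "T2_fluid",
            if (include_s0) "S0")
  pts <- expand.grid(b = b_values, te = te_values, KEEP.OUT.ATTRS = FALSE)
  if (nrow(pts) <= length(keep))
    stop("design has no more points (", nrow(pts),
         ") than parameters (", length(keep), ")")
  J <- .model_jac(p, pts$b, pts$te)[, keep, drop = FALSE]
  w <- if (is.null(averages)) rep(1, nrow(pts)) else
    rep(rep_len(averages, length(b_values)), times = length(te_values))
  Fi <- crossprod(J, w * J) / sigma^2
  ev <- eigen(Fi, symmetric = TRUE, only.values = TRUE)$values
  attr(Fi, "condition") <- max(ev) / max(min(ev), .Machine$double.xmin)
  Fi
}

#' Cramér–Rao lower bound on the SD of the perfusion fraction
#'
#' The square root of the (f, f) entry of the inverse Fisher information:
#' the smallest SD any unbiased estimator of f can achieve on the given
#' design at the given noise level.
#'
#' @inheritParams fisher_information
#' @return Scalar lower bound on SD(f).
#' @export
crlb_sd_f <- function(state, b_values, te_values, sigma, averages = NULL,
                      include_s0 = FALSE, reference_te = min(te_values)) {
  Fi <- fisher_information(state, b_values, te_values, sigma, averages,
                           include_s0, reference_te)
  inv <- tryCatch(solve(Fi), error = function(e) NULL)
  if (is.null(inv)) {
    ev <- eigen(Fi, symmetric = TRUE)
    dir <- paste(sprintf("%s=%.2g", colnames(Fi),
                         ev$vectors[, ncol(Fi)]), collapse = ", ")
    stop("singular information matrix (condition ",
         format(attr(Fi, "condition"), digits = 3),
         "); unidentifiable direction: ", dir)
  }
  sqrt(inv["f", "f"])
}

#' Echo-time design space for protocol optimization
#'
#' Describes the search problem: candidate TEs, the fixed b-values, the
#' subset size, the tissue preset and noise level, and the grid of fluid-T2
#' scenarios the objective is summed over.
#'
#' @param candidate_tes Candidate echo times in ms (unique; sorted
#'   internally).
#' @param b_values Fixed b-values in s/mm^2.
#' @param k Subset size, `<= length(candidate_tes)`.
#' @param state Tissue preset ([tissue_state()]); default liver at 3T.
#' @param t2_fluid_values Fluid-T2 evaluation grid in ms; default the
#'   liver grid 27–87 ms in 5 ms steps.
#' @param sigma Noise SD (default 0.025, i.e. SNR 40).
#' @param tr Repetition time in ms (used by Monte-Carlo validation;
#'   default 4000).
#' @param averages Optional per-b averages.
#' @return An object of class `"design_space"`.
#' @export
design_space <- function(candidate_tes, b_values, k,
                         state = tissue_preset("liver"),
                         t2_fluid_values = t2_fluid_grid("liver"),
                         sigma = 0.025, tr = 4000, averages = NULL) {
  candidate_tes <- sort(unique(as.numeric(candidate_tes)))
  if (k > length(candidate_tes))
    stop("subset size k exceeds the number of candidates")
  if (k < 1) stop("k must be >= 1")
  structure(list(candidate_tes = candidate_tes, b_values = b_values,
                 k = as.integer(k), state = state,
                 t2_fluid_values = t2_fluid_values, sigma = sigma,
                 tr = tr, averages = averages),
            class = "design_space")
}

#' nRMSE design objective for a TE subset
#'
#' The quantity the protocol search minimizes: over the fluid-T2 scenario
#' grid,
#' \deqn{\mathrm{nRMSE} = \sum_i \sqrt{\beta_i^2 + \sigma_{f,i}^2} / f,}
#' with `sigma_f` the CRLB SD of f ([crlb_sd_f()]) for that scenario and
#' `beta` the bias of f. By default `beta = 0`: the joint model is
#' correctly specified for its own data, so the asymptotic bias vanishes
#' and the objective is a sum of coefficients of variation. A small
#' Monte-Carlo plug-in bias (`bias = "mc"`) is available for callers who
#' want the finite-sample term.
#'
#' @param te_subset Echo times to evaluate (order irrelevant).
#' @param space A [design_space()].
#' @param bias `"zero"` (default) or `"mc"` (plug-in from `mc_reps`
#'   repetitions per scenario; slow).
#' @param mc_reps Repetitions for the plug-in bias.
#' @return Scalar objective (dimensionless, `> 0` for `sigma > 0`).
#' @export
nrmse_objective <- function(te_subset, space, bias = c("zero", "mc"),
                            mc_reps = 200) {
  bias <- match.arg(bias)
  stopifnot(inherits(space, "design_space"))
  f_true <- space$state$ivim$f
  total <- 0
  for (t2f in space$t2_fluid_values) {
    st <- space$state
    st$relax <- relaxation_params(st$relax$T1_tissue, st$relax$T1_fluid,
                                  st$relax$T2_tissue, t2f)
    sd_f <- tryCatch(
      crlb_sd_f(st, space$b_values, te_subset, space$sigma,
                averages = space$averages),
      error = function(e) stop("objective evaluation failed at T2_fluid = ",
                               t2f, " ms: ", conditionMessage(e)))
    beta <- 0
    if (bias == "mc") {
      grid <- acq_grid(space$b_values, sort(te_subset), space$tr,
                       averages = space$averages)
      mc <- run_monte_carlo(st, grid, noise_model(space$sigma), mc_reps,
                            mc_fitter_2d())
      beta <- mc$mean[["f"]] - f_true
    }
    total <- total + sqrt(beta^2 + sd_f^2) / f_true
  }
  total
}

#' Exhaustive TE-subset optimization
#'
#' Evaluates [nrmse_objective()] for every k-subset of the candidates and
#' returns the global minimizer. Deterministic; ties break toward the
#' lexicographically smallest subset. Serves as the ground-truth oracle for
#' the genetic-algorithm search.
#'
#' @param space A [design_space()].
#' @param max_evals Refuse searches larger than this many subsets
#'   (default 1e6).
#' @return An object of class `"design_result"`: `te_subset`, `objective`,
#'   per-scenario breakdown, `method`, `n_evals`.
#' @export
optimize_tes_exhaustive <- function(space, max_evals = 1e6) {
  stopifnot(inherits(space, "design_space"))
  n_sub <- choose(length(space$candidate_tes), space$k)
  if (n_sub > max_evals)
    stop("exhaustive search over ", n_sub, " subsets exceeds the budget; ",
         "use optimize_tes_ga()")
  subs <- utils::combn(space$candidate_tes, space$k)
  vals <- apply(subs, 2, nrmse_objective, space = space)
  best <- which(vals == min(vals))[1]  # combn order is lexicographic
  .design_result(subs[, best], vals[best], space, "exhaustive", ncol(subs))
}

.design_result <- function(te_subset, objective, space, method, n_evals) {
  per <- vapply(space$t2_fluid_values, function(t2f) {
    st <- space$state
    st$relax <- relaxation_params(st$relax$T1_tissue, st$relax$T1_fluid,
                                  st$relax$T2_tissue, t2f)
    crlb_sd_f(st, space$b_values, te_subset, space$sigma,
              averages = space$averages)
  }, numeric(1))
  structure(list(te_subset = sort(te_subset), objective = objective,
                 breakdown = data.frame(T2_fluid = space$t2_fluid_values,
                                        crlb_sd_f = per,
                                        beta = 0),
                 method = method, n_evals = n_evals, space = space),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("Optimal TE subset (%s search, %d evaluations):\n",
              x$method, x$n_evals))
  cat("  TEs (ms): ", paste(x$te_subset, collapse = ", "), "\n")
  cat(sprintf("  nRMSE objective: %.4f\n", x$objective))
  invisible(x)
}

#' Genetic-algorithm options
#'
#' @param population Population size (`>= 2`).
#' @param generations Generation cap.
#' @param ftol Stop when the best objective improves by less than this
#'   over `stall` consecutive generations.
#' @param elite_fraction Fraction of the fittest individuals copied
#'   unchanged into the next generation (default 0.05).
#' @param mutation_rate Per-gene probability of mutating to a random
#'   candidate.
#' @param stall Stall window for the tolerance stop.
#' @param seed Optional RNG seed.
#' @return An object of class `"ga_options"`.
#' @export
ga_options <- function(population = 10000, generations = 100, ftol = 0.001,
                       elite_fraction = 0.05, mutation_rate = 0.1,
                       stall = 10, seed = NULL) {
  if (population < 2) stop("population must be >= 2")
  if (elite_fraction <= 0 || elite_fraction >= 1)
    stop("elite_fraction must be in (0, 1)")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations), ftol = ftol,
                 elite_fraction = elite_fraction,
                 mutation_rate = mutation_rate, stall = as.integer(stall),
                 seed = seed),
            class = "ga_options")
}

#' Genetic-algorithm TE-subset optimization
#'
#' Integer-coded GA over k-subsets of the candidate echo times: each
#' chromosome is a set of k distinct candidate indices. Tournament
#' selection (size 2), uniform crossover with duplicate repair (clashing
#' genes are resampled from the unused candidates), per-gene mutation to a
#' random unused candidate, and elitism (the fittest `elite_fraction` of
#' the population survives unchanged). Terminates at the generation cap or
#' when the best objective has improved by less than `ftol` over the stall
#' window. Seeded runs are fully reproducible.
#'
#' @param space A [design_space()].
#' @param opts A [ga_options()].
#' @return A `"design_result"` (method `"ga"`).
#' @export
optimize_tes_ga <- function(space, opts = ga_options()) {
  stopifnot(inherits(space, "design_space"), inherits(opts, "ga_options"))
  if (!is.null(opts$seed)) set.seed(opts$seed)
  cands <- space$candidate_tes
  n <- length(cands); k <- space$k
  pop <- t(replicate(opts$population, sort(sample.int(n, k))))
  score_cache <- new.env(hash = TRUE, parent = emptyenv())
  n_evals <- 0L
  score_one <- function(idx) {
    key <- paste(idx, collapse = ",")
    v <- score_cache[[key]]
    if (is.null(v)) {
      v <- nrmse_objective(cands[idx], space)
      score_cache[[key]] <- v
      n_evals <<- n_evals + 1L
    }
    v
  }
  scores <- apply(pop, 1, score_one)
  n_elite <- max(1L, floor(opts$elite_fraction * opts$population))
  best_hist <- min(scores)
  for (gen in seq_len(opts$generations)) {
    ord <- order(scores)
    elite <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    children <- matrix(0L, opts$population - n_elite, k)
    for (i in seq_len(nrow(children))) {
      pick <- function() {  # tournament of 2
        cand2 <- sample.int(opts$population, 2)
        pop[cand2[which.min(scores[cand2])], ]
      }
      p1 <- pick(); p2 <- pick()
      take <- stats::runif(k) < 0.5           # uniform crossover
      child <- ifelse(take, p1, p2)
      # duplicate repair: resample clashes from the unused candidates
      dup <- duplicated(child)
      if (any(dup))
        child[dup] <- sample(setdiff(seq_len(n), child[!dup]), sum(dup))
      mut <- stats::runif(k) < opts$mutation_rate
      if (any(mut))
        child[mut] <- sample(setdiff(seq_len(n), child[!mut]),
                             sum(mut))
      children[i, ] <- sort(child)
    }
    pop <- rbind(elite, children)
    scores <- apply(pop, 1, score_one)
    best_hist <- c(best_hist, min(scores))
    ng <- length(best_hist)
    if (ng > opts$stall &&
        best_hist[ng - opts$stall] - best_hist[ng] < opts$ftol) break
  }
  best <- pop[which.min(scores), ]
  .design_result(cands[best], min(scores), space, "ga", n_evals)
}

#' Monte-Carlo validation of a TE protocol
#'
#' The full-pipeline check of a designed protocol: simulate Rician-noised
#' relaxation-compensated data on (b-values x TE subset), fit the joint 2D
#' T2-IVIM model to every repetition, and summarize the ensemble. Used to
#' confirm that the CRLB-based ranking of protocols carries over to actual
#' fitted variances.
#'
#' @param te_subset Echo times of the protocol.
#' @param space A [design_space()] (supplies b-values, preset, sigma, TR).
#' @param n_rep Number of repetitions.
#' @param seed Optional seed.
#' @param t2_fluid Fluid T2 for the generating state in ms (default: the
#'   median of the space's scenario grid).
#' @return An [run_monte_carlo()] summary.
#' @export
validate_protocol_mc <- function(te_subset, space, n_rep = 2500,
                                 seed = NULL,
                                 t2_fluid = stats::median(space$t2_fluid_values)) {
  stopifnot(inherits(space, "design_space"))
  st <- space$state
  st$relax <- relaxation_params(st$relax$T1_tissue, st$relax$T1_fluid,
                                st$relax$T2_tissue, t2_fluid)
  grid <- acq_grid(space$b_values, sort(te_subset), space$tr,
                   averages = space$averages)
  run_monte_carlo(st, grid, noise_model(space$sigma, seed = seed), n_rep,
                  mc_fitter_2d())
}

#' Canned fitters for Monte-Carlo pipelines
#'
#' Convenience wrappers turning the fitting functions into the
#' one-argument fitters [run_monte_carlo()] expects: `mc_fitter_2d()`
#' applies the joint 2D fit, `mc_fitter_1d(te)` the conventional fit to
#' one echo time's b-series.
#'
#' @param fit_s0 Fit a free scale (2D; default `NULL` = [fit_t2ivim()]'s
#'   normalization-driven choice).
#' @return A function `signal_dataset -> named estimates`.
#' @export
mc_fitter_2d <- function(fit_s0 = NULL) {
  function(ds) {
    fit <- fit_t2ivim(ds, fit_s0 = fit_s0, allow_relative_t2 = TRUE)
    est <- coef(fit)
    attr(est, "converged") <- fit$converged
    est
  }
}

#' @rdname mc_fitter_2d
#' @param te Echo time whose b-series the 1D fitter uses.
#' @export
mc_fitter_1d <- function(te) {
  force(te)
  function(ds) {
    ser <- extract_te_series(ds, te)
    fit <- fit_ivim(ser$signals, ser$b_values)
    est <- coef(fit)
    attr(est, "converged") <- fit$converged
    est
  }
}
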