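#' Parameters of the synthetic study-design generator
#'
#' The generator emulates a two-condition (low/high salt), two-replicate,
#' six-time-point continuous-light TPM time course: a minority of genes
#' carry a 24-h cosine signal with condition-dependent prevalence and
#' phase distribution, conditions differ by planted fold changes, and
#' every observation carries multiplicative log-normal noise.
#'
#' The expression value for gene g, condition c, replicate r, time t is
#' \deqn{B_g \cdot F_{g,c} \cdot (1 + A_{g,c} \cos(2\pi (t - \phi_{g,c}) / T)) \cdot \varepsilon}
#' with log-normal baseline `B`, condition factor `F = 2^log2fc`, planted
#' relative amplitude `A` (0 for arrhythmic genes) and i.i.d. log-normal
#' noise with mean 1 and coefficient of variation `noise_cv`.
#'
#' Defaults mirror the study design the package targets: 3843 genes,
#' times LL 4–34 h every 6 h, two replicates, cycling prevalences
#' 51/3843 (low salt) and 218/3843 (high salt) with one shared cycling
#' gene, up/down prevalences 1368/3843 and 446/3843, and phases uniform
#' over the cycle in low salt but concentrated at LL16 in high salt.
#'
#' @param n_genes Number of genes.
#' @param times_h Sampling times (hours in LL).
#' @param n_replicates Replicates per condition.
#' @param conditions Condition labels; first is the reference ("low").
#' @param frac_cycling_low,frac_cycling_high Fraction of genes planted
#'   as cycling in each condition.
#' @param n_shared_cycling Cycling genes shared between conditions.
#' @param amplitude_range Planted relative amplitudes are drawn uniformly
#'   from this interval (subset of (0, 1)).
#' @param phase_mode_low,phase_mode_high `"uniform_0_24"` (phases uniform
#'   over one period) or `"fixed_peak_16"` (all phases at LL16).
#' @param baseline_log10_tpm_mean,baseline_log10_tpm_sd Normal parameters
#'   of log10 baseline TPM.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param frac_up,frac_down Fractions of genes planted up-/down-regulated
#'   in the second (high) condition.
#' @param effect_log2fc Planted |log2 fold change| of regulated genes.
#' @param period_h Period of the planted oscillation (hours).
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the parameters.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 3843L,
                       times_h = c(4, 10, 16, 22, 28, 34),
                       n_replicates = 2L,
                       conditions = c("low_salt", "high_salt"),
                       frac_cycling_low = 51 / 3843,
                       frac_cycling_high = 218 / 3843,
                       n_shared_cycling = 1L,
                       amplitude_range = c(0.15, 0.6),
                       phase_mode_low = "uniform_0_24",
                       phase_mode_high = "fixed_peak_16",
                       baseline_log10_tpm_mean = 2,
                       baseline_log10_tpm_sd = 0.8,
                       noise_cv = 0.2,
                       frac_up = 1368 / 3843,
                       frac_down = 446 / 3843,
                       effect_log2fc = 2,
                       period_h = 24,
                       seed = 1L) {
  stopifnot(n_genes >= 1, length(times_h) >= 2, n_replicates >= 1,
            length(conditions) == 2,
            frac_cycling_low >= 0, frac_cycling_low <= 1,
            frac_cycling_high >= 0, frac_cycling_high <= 1,
            n_shared_cycling >= 0, noise_cv >= 0,
            length(amplitude_range) == 2,
            amplitude_range[1] > 0, amplitude_range[2] < 1,
            amplitude_range[1] <= amplitude_range[2],
            frac_up >= 0, frac_down >= 0, frac_up + frac_down <= 1,
            effect_log2fc >= 0, period_h > 0)
  modes <- c("uniform_0_24", "fixed_peak_16")
  stopifnot(phase_mode_low %in% modes, phase_mode_high %in% modes)
  structure(list(
    n_genes = as.integer(n_genes), times_h = sort(times_h),
    n_replicates = as.integer(n_replicates), conditions = conditions,
    frac_cycling_low = frac_cycling_low, frac_cycling_high = frac_cycling_high,
    n_shared_cycling = as.integer(n_shared_cycling),
    amplitude_range = amplitude_range,
    phase_mode_low = phase_mode_low, phase_mode_high = phase_mode_high,
    baseline_log10_tpm_mean = baseline_log10_tpm_mean,
    baseline_log10_tpm_sd = baseline_log10_tpm_sd,
    noise_cv = noise_cv, frac_up = frac_up, frac_down = frac_down,
    effect_log2fc = effect_log2fc, period_h = period_h,
    seed = as.integer(seed)), class = "sim_params")
}

draw_phases <- function(mode, n, period_h) {
  switch(mode,
         uniform_0_24 = runif(n, 0, period_h),
         fixed_peak_16 = rep(16, n))
}

#' Simulate an expression matrix with planted ground truth
#'
#' @param params A [sim_params()].
#' @return A list of class `cycle_sim` with elements
#'   * `expression`: long expression tibble (as [read_expression_table()]
#'     returns), sample ids like `low_salt_r1_LL04`;
#'   * `truth`: per gene x condition tibble with `is_cycling_true`,
#'     `true_relative_amplitude`, `true_peak_h`, and the per-gene
#'     `true_log2fc` and `true_category`.
#' @export
simulate_expression <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  n <- p$n_genes
  n_cyc_low <- round(p$frac_cycling_low * n)
  n_cyc_high <- round(p$frac_cycling_high * n)
  n_shared <- min(p$n_shared_cycling, n_cyc_low, n_cyc_high)
  if (n_cyc_low + n_cyc_high - n_shared > n) {
    abort("cycling fractions infeasible: planted sets exceed the gene count")
  }
  n_up <- round(p$frac_up * n)
  n_down <- round(p$frac_down * n)

  withr::with_seed(p$seed, {
    gene_id <- sprintf("G%04d", seq_len(n))
    baseline <- 10^rnorm(n, p$baseline_log10_tpm_mean, p$baseline_log10_tpm_sd)

    reg <- sample(n)                       # disjoint up/down sets
    up_idx <- reg[seq_len(n_up)]
    down_idx <- reg[n_up + seq_len(n_down)]
    log2fc <- numeric(n)
    log2fc[up_idx] <- p$effect_log2fc
    log2fc[down_idx] <- -p$effect_log2fc

    cyc <- sample(n)                       # shared genes first, then extras
    shared_idx <- cyc[seq_len(n_shared)]
    low_idx <- c(shared_idx, cyc[n_shared + seq_len(n_cyc_low - n_shared)])
    high_idx <- c(shared_idx,
                  cyc[n_cyc_low + seq_len(n_cyc_high - n_shared)])

    amp <- matrix(0, n, 2, dimnames = list(NULL, p$conditions))
    phase <- matrix(NA_real_, n, 2, dimnames = list(NULL, p$conditions))
    amp[low_idx, 1] <- runif(length(low_idx), p$amplitude_range[1],
                             p$amplitude_range[2])
    amp[high_idx, 2] <- runif(length(high_idx), p$amplitude_range[1],
                              p$amplitude_range[2])
    phase[low_idx, 1] <- draw_phases(p$phase_mode_low, length(low_idx),
                                     p$period_h)
    phase[high_idx, 2] <- draw_phases(p$phase_mode_high, length(high_idx),
                                      p$period_h)

    sdlog <- sqrt(log(1 + p$noise_cv^2))
    fac <- cbind(1, 2^log2fc)              # condition factor, low = reference

    blocks <- list()
    for (ci in seq_along(p$conditions)) {
      for (r in seq_len(p$n_replicates)) {
        for (t in p$times_h) {
          wave <- 1 + amp[, ci] *
            ifelse(is.na(phase[, ci]), 0,
                   cos(2 * pi * (t - phase[, ci]) / p$period_h))
          eps <- if (p$noise_cv > 0) rlnorm(n, -sdlog^2 / 2, sdlog) else 1
          blocks[[length(blocks) + 1]] <- tibble(
            gene_id = gene_id,
            sample_id = sprintf("%s_r%d_LL%02d", p$conditions[ci], r,
                                as.integer(t)),
            condition = p$conditions[ci],
            replicate = as.integer(r),
            time_ll_h = t,
            tpm = as.numeric(baseline * fac[, ci] * wave * eps))
        }
      }
    }
    expr <- arrange(bind_rows(blocks), match(.data$gene_id, gene_id))

    truth <- bind_rows(lapply(seq_along(p$conditions), function(ci) {
      tibble(gene_id = gene_id, condition = p$conditions[ci],
             is_cycling_true = amp[, ci] > 0,
             true_relative_amplitude = amp[, ci],
             true_peak_h = ifelse(is.na(phase[, ci]), NA_real_,
                                  phase[, ci] %% p$period_h),
             true_log2fc = log2fc,
             true_category = factor(
               case_when(log2fc >= 2 ~ "up_high",
                         log2fc >= 1 ~ "up",
                         log2fc <= -2 ~ "down_high",
                         log2fc <= -1 ~ "down",
                         .default = "unchanged"),
               levels = deg_category_levels))
    }))
    structure(list(expression = expr, truth = truth, params = p),
              class = "cycle_sim")
  })
}

#' Simulate a fully arrhythmic, effect-free dataset
#'
#' Calibration input: same marginal structure as [simulate_expression()]
#' but with all cycling fractions and condition effects set to zero, so
#' every gene is noise around its baseline.
#'
#' @param params A [sim_params()]; its cycling and effect fields are
#'   overridden to zero.
#' @return A `cycle_sim` whose truth table is all-negative.
#' @export
simulate_null_expression <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  params$frac_cycling_low <- 0
  params$frac_cycling_high <- 0
  params$n_shared_cycling <- 0L
  params$frac_up <- 0
  params$frac_down <- 0
  simulate_expression(params)
}

#' @export
print.cycle_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf("<cycle_sim> %d genes x %d samples (%d conditions x %d replicates x %d times), seed %d\n",
              p$n_genes,
              length(p$conditions) * p$n_replicates * length(p$times_h),
              length(p$conditions), p$n_replicates, length(p$times_h),
              p$seed))
  cyc <- x$truth |> group_by(.data$condition) |>
    summarise(n = sum(.data$is_cycling_true), .groups = "drop")
  cat("  planted cycling genes:",
      paste(sprintf("%s=%d", cyc$condition, cyc$n), collapse = ", "), "\n")
  invisible(x)
}
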