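#' Specify a synthetic imaging cohort
#'
#' Emulates the counting experiment behind the percent-PS-positive readout:
#' several coverslips, 10-20 random fields of view per coverslip, and a
#' per-cell phenotype draw. `constitutive_fraction` is the probability that
#' an expressing cell shows spontaneous PS exposure (AnV-positive without
#' stimulation); `scrambler_fraction` the probability that a non-constitutive
#' cell responds to the ionophore.
#'
#' @param n_coverslips Number of coverslips.
#' @param fields_per_coverslip Length-2 integer range, fields drawn
#'   uniformly from it (default `c(10, 20)`).
#' @param cells_per_field_mean Poisson mean of expressing cells per field.
#' @param scrambler_fraction Probability in `[0, 1]`.
#' @param constitutive_fraction Probability in `[0, 1]`.
#' @param t_half_mean_s,t_half_sd_s Mean and SD of the lognormal draw of
#'   true half-times for scrambler cells (seconds).
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_coverslips = 10L,
                        fields_per_coverslip = c(10L, 20L),
                        cells_per_field_mean = 15,
                        scrambler_fraction = 0.8,
                        constitutive_fraction = 0,
                        t_half_mean_s = 150, t_half_sd_s = 50,
                        seed = 1L) {
  stop_if_not(scrambler_fraction >= 0 && scrambler_fraction <= 1 &&
                constitutive_fraction >= 0 && constitutive_fraction <= 1,
              "fractions must lie in [0, 1]")
  stop_if_not(length(fields_per_coverslip) == 2L &&
                fields_per_coverslip[1] <= fields_per_coverslip[2],
              "fields_per_coverslip must be an increasing length-2 range")
  structure(list(n_coverslips = as.integer(n_coverslips),
                 fields_per_coverslip = as.integer(fields_per_coverslip),
                 cells_per_field_mean = cells_per_field_mean,
                 scrambler_fraction = scrambler_fraction,
                 constitutive_fraction = constitutive_fraction,
                 t_half_mean_s = t_half_mean_s, t_half_sd_s = t_half_sd_s,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of expressing cells
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with one row per cell: `coverslip`, `field`,
#'   `cell_id`, `phenotype` (`constitutive`, `scrambler` or
#'   `non_scrambler`), `ps_positive` (spontaneous PS exposure) and
#'   `t_half_true_s` (finite for scramblers, `0` for constitutive cells,
#'   `NA` otherwise).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  mu <- log(spec$t_half_mean_s^2 /
              sqrt(spec$t_half_mean_s^2 + spec$t_half_sd_s^2))
  sig <- sqrt(log(1 + (spec$t_half_sd_s / spec$t_half_mean_s)^2))
  with_seed(spec$seed, {
    rows <- list()
    for (cs in seq_len(spec$n_coverslips)) {
      n_fields <- sample(seq(spec$fields_per_coverslip[1],
                             spec$fields_per_coverslip[2]), 1L)
      for (fd in seq_len(n_fields)) {
        n <- stats::rpois(1L, spec$cells_per_field_mean)
        if (n == 0L) next
        u <- stats::runif(n)
        pheno <- ifelse(u < spec$constitutive_fraction, "constitutive",
                        ifelse(u < spec$constitutive_fraction +
                                 (1 - spec$constitutive_fraction) *
                                 spec$scrambler_fraction,
                               "scrambler", "non_scrambler"))
        th <- ifelse(pheno == "scrambler",
                     stats::rlnorm(n, mu, sig),
                     ifelse(pheno == "constitutive", 0, NA_real_))
        rows[[length(rows) + 1L]] <- data.frame(
          coverslip = cs, field = fd,
          cell_id = sprintf("cs%d_f%d_c%d", cs, fd, seq_len(n)),
          phenotype = pheno, ps_positive = pheno == "constitutive",
          t_half_true_s = th, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("cohort", "data.frame")
    out
  })
}

#' Per-field expressing / PS-positive counts of a cohort
#'
#' @param cohort Output of [generate_cohort()].
#' @return Data frame `coverslip`, `field`, `n_expressing`,
#'   `n_ps_positive`, suitable for [percent_ps_positive()] per coverslip.
#' @export
cohort_field_counts <- function(cohort) {
  agg <- stats::aggregate(
    cbind(n_expressing = rep(1L, nrow(cohort)),
          n_ps_positive = as.integer(cohort$ps_positive)),
    by = list(coverslip = cohort$coverslip, field = cohort$field), FUN = sum)
  agg[order(agg$coverslip, agg$field), ]
}

#' Per-coverslip percent-PS-positive summaries of a cohort
#'
#' @param cohort Output of [generate_cohort()].
#' @return Data frame of per-coverslip summaries (one row each).
#' @export
cohort_ps_summary <- function(cohort) {
  cnt <- cohort_field_counts(cohort)
  out <- lapply(split(cnt, cnt$coverslip), function(d)
    percent_ps_positive(d, coverslip_id = d$coverslip[1]))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
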