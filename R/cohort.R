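#' Specification of a synthetic treatment cohort
#'
#' Describes a cohort of tumor-bearing animals with known response classes.
#' Each animal draws a true tumor volume response (TVR, the percentage
#' change in caliper volume over treatment) strictly inside its class
#' interval, so classification of the generated values always recovers the
#' generating class. A linear coupling with additive Gaussian noise links
#' the true volume change to the true change in lesion SUVmax, emulating
#' the empirical association between volumetric response and tracer-uptake
#' response.
#'
#' The default effect ranges are bounded by the span observed in treated
#' xenografts (roughly -84% for the strongest partial response up to +181%
#' for the strongest progression): PR in (-90, -30), SD in (-30, +20],
#' PD in (+20, +200].
#'
#' @param n_animals number of animals.
#' @param class_fractions named numeric, proportions of `PR`, `SD`, `PD`;
#'   must sum to 1. Counts are apportioned by largest remainder so the
#'   realized composition is deterministic.
#' @param tvr_ranges named list of `c(lo, hi)` true-TVR intervals (percent)
#'   per class. Sampling is strictly interior, and every interval must be
#'   consistent with the classification cuts (`pr_cut`, `pd_cut`).
#' @param pr_cut,pd_cut classification thresholds (percent) the generated
#'   cohort must round-trip through, see [classify_tvr()].
#' @param uptake_coupling slope linking true TVR to true delta-SUVmax
#'   (percent per percent).
#' @param uptake_noise_sd SD (percentage points) of the coupling noise.
#' @param pre_volume_range range (mm^3) for baseline caliper volumes,
#'   sampled log-uniformly; spans the small (< 150 mm^3) and large strata.
#' @param pre_suvmax_range range for baseline lesion SUVmax.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_animals = 13,
                        class_fractions = c(PR = 4 / 13, SD = 5 / 13,
                                            PD = 4 / 13),
                        tvr_ranges = list(PR = c(-90, -30),
                                          SD = c(-30, 20),
                                          PD = c(20, 200)),
                        pr_cut = -30, pd_cut = 20,
                        uptake_coupling = 1.0,
                        uptake_noise_sd = 10,
                        pre_volume_range = c(40, 580),
                        pre_suvmax_range = c(6, 12)) {
  if (n_animals < 1) stop("'n_animals' must be >= 1")
  if (!setequal(names(class_fractions), c("PR", "SD", "PD")))
    stop("'class_fractions' must be named PR, SD, PD")
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop("'class_fractions' must sum to 1 (got ",
         format(sum(class_fractions)), ")")
  if (any(class_fractions < 0)) stop("class fractions must be >= 0")
  for (cl in c("PR", "SD", "PD")) {
    r <- tvr_ranges[[cl]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2])
      stop("tvr_ranges$", cl, " must be c(lo, hi) with lo <= hi")
  }
  # intervals must sit inside the region classify_tvr maps to that class
  if (tvr_ranges$PR[2] > pr_cut)
    stop("PR interval must lie at or below pr_cut = ", pr_cut)
  if (tvr_ranges$SD[1] < pr_cut || tvr_ranges$SD[2] > pd_cut)
    stop("SD interval must lie within (pr_cut, pd_cut]")
  if (tvr_ranges$PD[1] < pd_cut)
    stop("PD interval must lie above pd_cut = ", pd_cut)
  if (uptake_noise_sd < 0) stop("'uptake_noise_sd' must be >= 0")
  structure(list(n_animals = as.integer(n_animals),
                 class_fractions = class_fractions[c("PR", "SD", "PD")],
                 tvr_ranges = tvr_ranges, pr_cut = pr_cut, pd_cut = pd_cut,
                 uptake_coupling = uptake_coupling,
                 uptake_noise_sd = uptake_noise_sd,
                 pre_volume_range = pre_volume_range,
                 pre_suvmax_range = pre_suvmax_range),
            class = "cohort_spec")
}

# largest-remainder apportionment of n into fractions
.apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# uniform draw strictly inside (lo, hi): degenerate lo == hi returns lo
.runif_open <- function(n, lo, hi) {
  if (lo == hi) return(rep(lo, n))
  eps <- (hi - lo) * 1e-9
  stats::runif(n, lo + eps, hi - eps)
}

#' Generate a synthetic cohort with known response classes
#'
#' Draws per-animal true TVR values strictly inside each class interval,
#' derives post-treatment caliper volumes from the baseline volumes, and
#' couples the uptake response (delta-SUVmax) to the volume response
#' linearly with Gaussian noise (clamped above -99%, since uptake cannot
#' fall below zero).
#'
#' @param spec a [cohort_spec()].
#' @param seed integer RNG seed.
#' @return A data.frame of class `pet_cohort` with columns `animal_id`,
#'   `true_class`, `pre_volume_mm3`, `post_volume_mm3`, `true_tvr`,
#'   `pre_suvmax`, `post_suvmax`, `true_d_suvmax`.
#' @export
#' @examples
#' coh <- make_cohort(cohort_spec(), seed = 7)
#' table(coh$true_class)
make_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed %% .Machine$integer.max))
  counts <- .apportion(spec$n_animals, spec$class_fractions)
  classes <- rep(c("PR", "SD", "PD"), counts)
  n <- spec$n_animals
  tvr <- numeric(n)
  for (cl in c("PR", "SD", "PD")) {
    idx <- classes == cl
    r <- spec$tvr_ranges[[cl]]
    tvr[idx] <- .runif_open(sum(idx), r[1], r[2])
  }
  pre_vol <- exp(stats::runif(n, log(spec$pre_volume_range[1]),
                              log(spec$pre_volume_range[2])))
  post_vol <- pre_vol * (1 + tvr / 100)
  pre_suv <- stats::runif(n, spec$pre_suvmax_range[1],
                          spec$pre_suvmax_range[2])
  d_suv <- spec$uptake_coupling * tvr +
    stats::rnorm(n, 0, spec$uptake_noise_sd)
  d_suv <- pmax(d_suv, -99)
  post_suv <- pre_suv * (1 + d_suv / 100)
  out <- data.frame(animal_id = sprintf("animal%02d", seq_len(n)),
                    true_class = factor(classes,
                                        levels = c("PR", "SD", "PD")),
                    pre_volume_mm3 = pre_vol, post_volume_mm3 = post_vol,
                    true_tvr = tvr,
                    pre_suvmax = pre_suv, post_suvmax = post_suv,
                    true_d_suvmax = d_suv,
                    stringsAsFactors = FALSE)
  class(out) <- c("pet_cohort", "data.frame")
  attr(out, "spec") <- spec
  out
}

#' Write a cohort table as CSV
#'
#' Columns follow the cross-tool convention
#' `animal_id,true_class,pre_volume_mm3,post_volume_mm3,pre_suvmax,post_suvmax`.
#'
#' @param cohort a `pet_cohort` from [make_cohort()].
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[, c("animal_id", "true_class", "pre_volume_mm3",
                              "post_volume_mm3", "pre_suvmax",
                              "post_suvmax")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
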