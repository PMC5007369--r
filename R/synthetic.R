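#' Configuration for the synthetic gel-set generator
#'
#' Collects and validates the parameters of the generative model used by
#' [simulate_gelset()].  Defaults mirror the design of the dual-channel
#' PBMC study the pipeline targets: 635 detectable spots, paired Asc+/Asc-
#' gels per subject, and a technical coefficient of variation just under
#' 9 percent.
#'
#' @param n_subjects_per_group subjects per group (NH and HF); `>= 2`.
#' @param n_spots number of protein spots.
#' @param frac_abundance_diff fraction of spots with a true abundance
#'   difference between groups, in `[0, 1]`.
#' @param frac_sno_diff fraction of spots with a true S-NO occupancy
#'   difference, in `[0, 1]`.
#' @param abundance_effect_fold linear fold (> 1) applied to affected
#'   spots in the HF group; the up/down direction is drawn per spot.
#' @param sno_quench_base baseline S-NO occupancy (fraction of cysteines
#'   nitrosylated, hence not dye-reactive in the Asc- channel), in `[0, 1)`.
#' @param sno_quench_effect signed occupancy change in the HF group for
#'   affected spots; `sno_quench_base + max(0, sno_quench_effect)` must be
#'   `< 1` and `sno_quench_base + min(0, sno_quench_effect)` must be `>= 0`.
#' @param bias_log_sd standard deviation of the per-gel log bias factor.
#' @param technical_cov technical coefficient of variation of replicate
#'   spot volumes (multiplicative log-normal noise); `> 0`.
#' @param biological_cov between-subject coefficient of variation of the
#'   latent biological volume, shared by the two channels of a subject.
#' @param frac_missing fraction of volume entries zeroed at random to
#'   emulate undetected spots.
#' @param seed integer seed; one seed governs every draw.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects_per_group = 30,
                             n_spots = 635,
                             frac_abundance_diff = 0,
                             frac_sno_diff = 0,
                             abundance_effect_fold = 2,
                             sno_quench_base = 0.3,
                             sno_quench_effect = 0,
                             bias_log_sd = 0.2,
                             technical_cov = 0.09,
                             biological_cov = 0,
                             frac_missing = 0,
                             seed = 1L) {
  cfg <- list(n_subjects_per_group = n_subjects_per_group, n_spots = n_spots,
              frac_abundance_diff = frac_abundance_diff,
              frac_sno_diff = frac_sno_diff,
              abundance_effect_fold = abundance_effect_fold,
              sno_quench_base = sno_quench_base,
              sno_quench_effect = sno_quench_effect,
              bias_log_sd = bias_log_sd, technical_cov = technical_cov,
              biological_cov = biological_cov, frac_missing = frac_missing,
              seed = seed)
  .chk <- function(field, ok) {
    if (!isTRUE(ok)) {
      stop("invalid synthetic_config field '", field, "' (value: ",
           format(cfg[[field]]), ")", call. = FALSE)
    }
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  .chk("n_subjects_per_group",
       num1(n_subjects_per_group) && n_subjects_per_group >= 2 &&
         n_subjects_per_group == round(n_subjects_per_group))
  .chk("n_spots", num1(n_spots) && n_spots >= 1 && n_spots == round(n_spots))
  .chk("frac_abundance_diff", num1(frac_abundance_diff) &&
         frac_abundance_diff >= 0 && frac_abundance_diff <= 1)
  .chk("frac_sno_diff", num1(frac_sno_diff) &&
         frac_sno_diff >= 0 && frac_sno_diff <= 1)
  .chk("abundance_effect_fold", num1(abundance_effect_fold) &&
         abundance_effect_fold >= 1)
  .chk("sno_quench_base", num1(sno_quench_base) &&
         sno_quench_base >= 0 && sno_quench_base < 1)
  .chk("sno_quench_effect", num1(sno_quench_effect) &&
         sno_quench_base + max(0, sno_quench_effect) < 1 &&
         sno_quench_base + min(0, sno_quench_effect) >= 0)
  .chk("bias_log_sd", num1(bias_log_sd) && bias_log_sd >= 0)
  .chk("technical_cov", num1(technical_cov) && technical_cov > 0)
  .chk("biological_cov", num1(biological_cov) && biological_cov >= 0)
  .chk("frac_missing", num1(frac_missing) && frac_missing >= 0 && frac_missing < 1)
  .chk("seed", num1(seed) && seed == round(seed))
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "synthetic_config")
}

# multiplicative log-normal factor with mean 1 and the requested CoV:
# sdlog^2 = log(1 + cov^2), meanlog = -sdlog^2/2
.lnorm_noise <- function(n, cov) {
  if (cov <= 0) return(rep(1, n))
  s2 <- log1p(cov^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

#' Simulate a two-group, two-channel gel set with known ground truth
#'
#' Generative model: each spot carries a baseline intensity drawn
#' log-uniformly over three orders of magnitude.  A subject's latent
#' biological volume is the baseline times the group abundance factor
#' (affected spots in HF only) times optional between-subject noise, and
#' is shared by the subject's paired Asc+ and Asc- fractions.  The Asc+
#' gel observes the latent volume under an independent per-gel bias
#' `exp(N(0, bias_log_sd))` and multiplicative technical noise with the
#' configured CoV.  The Asc- gel observes the latent volume scaled by
#' `1 - occupancy` — S-nitrosylated cysteines quench the maleimide dye
#' signal linearly in occupancy — under its own bias and noise.
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `gelset` (a [gelset()] of
#'   `4 * n_subjects_per_group` gels) and `truth`, a data.frame with one
#'   row per spot: `spot_id`, `true_abundance_fold` (signed fold, 1 for
#'   unaffected spots), `true_sno_direction`
#'   (`increased`/`decreased`/`unchanged`), and the per-group occupancies
#'   `quench_NH`, `quench_HF`.
#' @examples
#' sim <- simulate_gelset(synthetic_config(n_subjects_per_group = 3,
#'                                         n_spots = 20, seed = 7))
#' sim$gelset
#' @export
simulate_gelset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  c_ <- config
  set.seed(c_$seed)
  ns <- c_$n_spots
  nsub <- c_$n_subjects_per_group
  spot_ids <- sprintf("s%04d", seq_len(ns))

  mu <- 10^stats::runif(ns, 3, 6)

  n_ab <- round(c_$frac_abundance_diff * ns)
  n_sno <- round(c_$frac_sno_diff * ns)
  ab_idx <- if (n_ab > 0) sample.int(ns, n_ab) else integer(0)
  sno_idx <- if (n_sno > 0) sample.int(ns, n_sno) else integer(0)

  true_fold <- rep(1, ns)
  if (n_ab > 0) {
    up <- sample(c(TRUE, FALSE), n_ab, replace = TRUE)
    true_fold[ab_idx] <- ifelse(up, c_$abundance_effect_fold,
                                -c_$abundance_effect_fold)
  }
  quench_NH <- rep(c_$sno_quench_base, ns)
  quench_HF <- quench_NH
  quench_HF[sno_idx] <- c_$sno_quench_base + c_$sno_quench_effect
  true_dir <- rep("unchanged", ns)
  if (c_$sno_quench_effect > 0) true_dir[sno_idx] <- "increased"
  if (c_$sno_quench_effect < 0) true_dir[sno_idx] <- "decreased"

  n_gels <- 4L * nsub
  vol <- matrix(0, ns, n_gels)
  gel_id <- character(n_gels)
  meta <- data.frame(gel_id = character(n_gels), subject_id = character(n_gels),
                     group = character(n_gels), channel = character(n_gels),
                     stringsAsFactors = FALSE)
  g <- 0L
  for (group in .GROUPS) {
    ab_factor <- if (group == "HF") fold_to_linear(true_fold) else rep(1, ns)
    quench <- if (group == "HF") quench_HF else quench_NH
    for (i in seq_len(nsub)) {
      subject <- sprintf("%s%02d", group, i)
      latent <- mu * ab_factor * .lnorm_noise(ns, c_$biological_cov)
      for (channel in .CHANNELS) {
        g <- g + 1L
        gel_bias <- exp(stats::rnorm(1, 0, c_$bias_log_sd))
        base <- if (channel == "Asc+") latent else latent * (1 - quench)
        vol[, g] <- base * gel_bias * .lnorm_noise(ns, c_$technical_cov)
        gel_id[g] <- paste0(subject, "_", if (channel == "Asc+") "pos" else "neg")
        meta[g, ] <- list(gel_id[g], subject, group, channel)
      }
    }
  }
  if (c_$frac_missing > 0) {
    drop <- which(stats::runif(length(vol)) < c_$frac_missing)
    vol[drop] <- 0
  }
  dimnames(vol) <- list(spot_ids, gel_id)

  truth <- data.frame(spot_id = spot_ids,
                      true_abundance_fold = true_fold,
                      true_sno_direction = true_dir,
                      quench_NH = quench_NH, quench_HF = quench_HF,
                      stringsAsFactors = FALSE)
  list(gelset = gelset(vol, meta), truth = truth)
}

#' Write simulation ground truth as TSV
#'
#' @param truth the `truth` data.frame from [simulate_gelset()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Saturation-labeling dye and quencher concentrations
#'
#' Worked stoichiometry for thiol-saturating maleimide labeling: the dye
#' amount is the sample's total cysteine thiol content times the desired
#' molar excess, and the reaction is stopped with 2-mercaptoethanol at a
#' molar excess over the dye.  Concentrations are reported in umol/mL of
#' reaction volume.
#'
#' @param protein_mass_ug protein input, micrograms.
#' @param cys_density_pmol_per_ug cysteine thiol density, pmol per ug of
#'   protein (about 200 for human cell lysates).
#' @param dye_excess fold molar excess of dye over thiol.
#' @param reaction_volume_ul reaction volume, microliters.
#' @param quench_excess fold molar excess of quencher over dye.
#' @return named numeric vector `c(dye_umol_per_ml, quencher_umol_per_ml)`.
#' @examples
#' dye_stoichiometry(100, 200, 60, 200, 10)  # 6 umol/mL dye, 60 umol/mL 2-ME
#' @export
dye_stoichiometry <- function(protein_mass_ug, cys_density_pmol_per_ug,
                              dye_excess, reaction_volume_ul, quench_excess) {
  args <- c(protein_mass_ug = protein_mass_ug,
            cys_density_pmol_per_ug = cys_density_pmol_per_ug,
            dye_excess = dye_excess, reaction_volume_ul = reaction_volume_ul,
            quench_excess = quench_excess)
  bad <- !is.finite(args) | args <= 0
  if (any(bad)) {
    stop("all stoichiometry inputs must be positive (offending: '",
         names(args)[bad][1L], "')", call. = FALSE)
  }
  # pmol / uL = nmol / mL; divide by 1000 for umol / mL
  dye <- protein_mass_ug * cys_density_pmol_per_ug * dye_excess /
    reaction_volume_ul / 1000
  c(dye_umol_per_ml = dye, quencher_umol_per_ml = dye * quench_excess)
}
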