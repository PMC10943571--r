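#' Planted effects for the synthetic cohort
#'
#' Coefficients of the linear models from which cohort outcomes are
#' generated: each outcome is
#' `intercept + status*I(case) + epvs*ePVS_z + interaction*I(case)*ePVS_z +
#' age*(age-51) + sexF + education*(edu-16) + N(0, sd)`.
#' Defaults mirror the scale of the study cohort (24 CADASIL-like cases vs
#' 24 controls; ePVS volumes lognormal around 520 mm^3 with no group
#' difference; WMH volumes an order of magnitude larger in cases; interaction
#' slopes of the size reported for WMH/CDR-SB/MMSE/BPF). Outcomes are exactly
#' linear-Gaussian — no clipping — so planted coefficients are recoverable by
#' ordinary least squares; tail values outside physiological ranges are
#' accepted as the price of exact recoverability.
#'
#' @param interaction Named overrides for interaction slopes.
#' @param epvs_meanlog,epvs_sdlog Lognormal parameters of ePVS volume (mm^3).
#' @param analyte_effect Standardized effect (correlation with ePVS z-score)
#'   of associated analytes.
#' @param analyte_meanlog,analyte_sdlog Log-RFU location/scale.
#' @return An `effect_spec` list with components `epvs`, `outcomes`,
#'   `analytes`.
#' @export
cohort_effects <- function(interaction = NULL,
                           epvs_meanlog = 5.82, epvs_sdlog = 0.92,
                           analyte_effect = 0.8,
                           analyte_meanlog = 7, analyte_sdlog = 0.5) {
  if (epvs_sdlog <= 0) stop("degenerate effect spec: zero-variance ePVS")
  outcomes <- list(
    WMH_mm3 = c(intercept = 1306, status = 11417, epvs = 15,
                interaction = 2500, age = 0, sexF = 0, education = 0, sd = 5500),
    BPF = c(intercept = 0.78, status = -0.01, epvs = 0.001,
            interaction = -0.03, age = -0.0005, sexF = 0, education = 0, sd = 0.04),
    CDR_global = c(intercept = 0.02, status = 0.15, epvs = 0,
                   interaction = 0, age = 0, sexF = 0, education = 0, sd = 0.15),
    CDRBox = c(intercept = 0.15, status = 0.28, epvs = -0.03,
               interaction = 0.52, age = 0, sexF = 0, education = 0, sd = 0.55),
    MMSE = c(intercept = 29.5, status = -1.4, epvs = 0.11,
             interaction = -1.49, age = -0.02, sexF = 0, education = 0.05, sd = 1.2),
    TRAILB = c(intercept = 47.9, status = 25, epvs = -12,
               interaction = 43, age = 0.5, sexF = 0, education = -0.5, sd = 30),
    Rey10m = c(intercept = 13.36, status = -1.12, epvs = -0.1,
               interaction = 0, age = -0.02, sexF = 0, education = 0.05, sd = 2.1)
  )
  if (!is.null(interaction)) {
    for (nm in names(interaction)) {
      if (!nm %in% names(outcomes)) stop("unknown outcome: ", nm)
      outcomes[[nm]]["interaction"] <- interaction[[nm]]
    }
  }
  structure(list(
    epvs = c(meanlog = epvs_meanlog, sdlog = epvs_sdlog),
    outcomes = outcomes,
    analytes = c(effect = analyte_effect, meanlog = analyte_meanlog,
                 sdlog = analyte_sdlog)
  ), class = "effect_spec")
}

#' Generate a synthetic case/control cohort with planted effects
#'
#' Produces a subject table (demographics, imaging outcomes, cognitive
#' scores) generated from the linear and interaction models the statistics
#' layer fits, with known coefficients, plus a subjects x analytes RFU
#' matrix in which a stated subset of analytes is linearly coupled to the
#' ePVS volume z-score. Deterministic given `seed` (base R Mersenne-Twister).
#'
#' @param n_cases,n_controls Group sizes (defaults 24/24, the study design).
#' @param effect_spec An [cohort_effects()] specification.
#' @param n_analytes Number of analytes (default 100).
#' @param n_associated Number of analytes coupled to ePVS (default 10; the
#'   first `n_associated` probes).
#' @param seed RNG seed.
#' @return List: `subjects` (data frame), `analytes` (matrix, rownames =
#'   subject ids, colnames = probe ids), `analyte_info` (probe id, protein
#'   symbol, associated flag), `effects` (the resolved spec).
#' @export
generate_cohort <- function(n_cases = 24L, n_controls = 24L,
                            effect_spec = cohort_effects(),
                            n_analytes = 100L, n_associated = 10L,
                            seed = 1L) {
  stopifnot(n_cases >= 0, n_controls >= 0, n_cases + n_controls >= 3,
            n_analytes >= 0, n_associated <= n_analytes,
            inherits(effect_spec, "effect_spec"))
  set.seed(seed)
  n <- n_cases + n_controls
  status <- rep(c("CADASIL", "control"), c(n_cases, n_controls))
  s01 <- as.numeric(status == "CADASIL")
  age <- round(stats::rnorm(n, mean = 51.8, sd = 11.8), 1)
  sex <- ifelse(stats::runif(n) < 2 / 3, "F", "M")
  education <- round(stats::rnorm(n, mean = 16 - 1.2 * s01, sd = 2.8), 1)
  epvs <- stats::rlnorm(n, effect_spec$epvs["meanlog"], effect_spec$epvs["sdlog"])
  epvs_z <- zscore(epvs)
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    status = status, age = age, sex = sex, education = education,
    ePVS_mm3 = epvs, ePVS_z = epvs_z
  )
  for (nm in names(effect_spec$outcomes)) {
    b <- effect_spec$outcomes[[nm]]
    subjects[[nm]] <- b["intercept"] + b["status"] * s01 + b["epvs"] * epvs_z +
      b["interaction"] * s01 * epvs_z + b["age"] * (age - 51) +
      b["sexF"] * (sex == "F") + b["education"] * (education - 16) +
      stats::rnorm(n, sd = b["sd"])
  }
  an <- effect_spec$analytes
  analytes <- NULL
  analyte_info <- NULL
  if (n_analytes > 0L) {
    z <- matrix(stats::rnorm(n * n_analytes), n, n_analytes)
    if (n_associated > 0L) {
      eff <- an["effect"]
      mix <- sqrt(max(0, 1 - eff^2))
      z[, seq_len(n_associated)] <- eff * epvs_z +
        mix * z[, seq_len(n_associated), drop = FALSE]
    }
    analytes <- exp(an["meanlog"] + an["sdlog"] * z)
    probe_id <- sprintf("seq.%04d.%d", 1000 + seq_len(n_analytes),
                        seq_len(n_analytes) %% 9 + 1)
    # every 25th probe duplicates the previous probe's protein, so protein
    # sets deduplicate below the probe count (as real aptamer panels do)
    sym_idx <- seq_len(n_analytes)
    dup <- which(sym_idx %% 25 == 0 & sym_idx > 1)
    sym_idx[dup] <- sym_idx[dup] - 1L
    symbol <- sprintf("PROT%04d", sym_idx)
    dimnames(analytes) <- list(subjects$subject_id, probe_id)
    analyte_info <- data.frame(probe_id = probe_id, symbol = symbol,
                               associated = seq_len(n_analytes) <= n_associated)
  }
  list(subjects = subjects, analytes = analytes, analyte_info = analyte_info,
       effects = effect_spec)
}

#' Read a subject table from CSV/TSV
#'
#' @param path File path; tab-separated when the extension is `.tsv`.
#' @return Data frame.
#' @export
read_subject_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}
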