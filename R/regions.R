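#' Region metadata for the default volumetric atlas
#'
#' The default feature set mirrors a standard surface-based parcellation:
#' 34 cortical regions per hemisphere (Desikan-Killiany) and 17 subcortical
#' volumes (8 per hemisphere plus the brain stem), i.e. 85 raw columns that
#' average down to 43 bilateral regions. Each bilateral region carries a
#' plausible mean volume (mm\eqn{^3}), a covariance-block label used by the
#' synthetic generator and as ground truth for clustering, and a sub-block
#' label splitting the temporo-limbic block into a cortical-temporal and a
#' subcortical-limbic group.
#'
#' @return A tibble with one row per raw (lateralized) region: `region`,
#'   `base_region`, `compartment` (`"cortical"`/`"subcortical"`),
#'   `hemisphere` (`"left"`, `"right"`, `"midline"`).
#' @export
#' @examples
#' dk_regions()
dk_regions <- function() {
  base <- region_base_table()
  paired <- base[base$base_region != "brainstem", ]
  lh <- paired %>%
    mutate(region = paste0("lh_", .data$base_region), hemisphere = "left")
  rh <- paired %>%
    mutate(region = paste0("rh_", .data$base_region), hemisphere = "right")
  mid <- base[base$base_region == "brainstem", ] %>%
    mutate(region = .data$base_region, hemisphere = "midline")
  bind_rows(lh, rh, mid) %>%
    select("region", "base_region", "compartment", "hemisphere")
}

#' Covariance-block assignment of the bilateral regions
#'
#' Five covariance blocks group the 43 bilateral regions: (1) occipito-parietal,
#' (2) fronto-central, (3) temporo-limbic, (4) cingulate/polar, and (5) a
#' brain-stem/basal group. Block 3 splits into a cortical-temporal sub-block
#' and a subcortical-limbic sub-block. These labels are the generating truth
#' of the simulator and the reference partition for clustering-recovery tests.
#'
#' @return A tibble: `base_region`, `block` (1-5), `subblock` (within block 3:
#'   `"temporal"` or `"limbic"`, otherwise `NA`).
#' @export
region_blocks <- function() {
  region_base_table() %>%
    select("base_region", "block", "subblock")
}

# Single source of truth for the bilateral regions: plausible mean volumes
# (mm^3, per-hemisphere average), residual noise CVs (after age/ICV/site),
# block structure and sub-factor loadings. Values are the simulator defaults.
region_base_table <- function() {
  tribble_df <- function(...) as_tibble(data.frame(..., stringsAsFactors = FALSE))
  cortical <- tribble_df(
    base_region = c(
      # block 1: occipito-parietal
      "cuneus", "isthmuscingulate", "lateraloccipital", "lingual",
      "pericalcarine", "precuneus", "superiorparietal",
      # block 2: fronto-central (caudalmiddlefrontal placed here; the
      # anterior cingulate sits in block 4)
      "caudalmiddlefrontal", "lateralorbitofrontal", "medialorbitofrontal",
      "paracentral", "parsopercularis", "parsorbitalis", "parstriangularis",
      "postcentral", "posteriorcingulate", "precentral", "rostralmiddlefrontal",
      "superiorfrontal", "superiortemporal", "supramarginal",
      "transversetemporal", "insula",
      # block 3, temporal sub-block
      "bankssts", "fusiform", "inferiorparietal", "inferiortemporal",
      "middletemporal",
      # block 3, limbic sub-block (cortical member)
      "parahippocampal",
      # block 4: cingulate / polar
      "caudalanteriorcingulate", "entorhinal", "rostralanteriorcingulate",
      "frontalpole", "temporalpole"
    ),
    baseline = c(
      3000, 2600, 11500, 6500, 2200, 9800, 12500,
      6500, 7500, 5000, 3500, 4500, 2300, 3900, 9500, 3100, 13000, 15500,
      21000, 11500, 9800, 1100, 6700,
      2500, 9500, 13000, 10500, 10500,
      2100,
      2000, 1900, 2400, 900, 2300
    ),
    block = c(rep(1L, 7), rep(2L, 16), rep(3L, 6), rep(4L, 5)),
    compartment = "cortical"
  )
  subcortical <- tribble_df(
    base_region = c(
      "thalamus", "putamen", "hippocampus", "amygdala", "accumbens",
      "caudate", "pallidum", "cerebellum", "brainstem"
    ),
    baseline = c(7200, 4900, 3900, 1600, 550, 3500, 1800, 52000, 21000),
    block = c(3L, 3L, 3L, 3L, 3L, 5L, 5L, 5L, 5L),
    compartment = "subcortical"
  )
  out <- bind_rows(cortical, subcortical)
  limbic <- c("parahippocampal", "thalamus", "putamen", "hippocampus",
              "amygdala", "accumbens")
  temporal <- c("bankssts", "fusiform", "inferiorparietal", "inferiortemporal",
                "middletemporal")
  out$subblock <- ifelse(out$base_region %in% limbic, "limbic",
                         ifelse(out$base_region %in% temporal, "temporal", NA))
  # residual (post-confounder) coefficient of variation of the noise term
  cv <- rep(0.08, nrow(out))
  cv[out$base_region == "parahippocampal"] <- 0.09
  cv_sub <- c(thalamus = 0.055, putamen = 0.065, hippocampus = 0.07,
              amygdala = 0.09, accumbens = 0.08, caudate = 0.07,
              pallidum = 0.075, cerebellum = 0.06, brainstem = 0.06)
  idx <- match(out$base_region, names(cv_sub))
  cv[!is.na(idx)] <- cv_sub[idx[!is.na(idx)]]
  out$noise_cv <- cv
  # loading of the sub-block shared factor (correlation between two members
  # of the same sub-block = block_loading^2 + subblock_loading_i*loading_j)
  lo <- rep(sqrt(0.20), nrow(out))
  lo_limbic <- c(thalamus = 0.55, putamen = 0.55, hippocampus = 0.55,
                 amygdala = 0.50, parahippocampal = 0.35, accumbens = 0.35)
  idx <- match(out$base_region, names(lo_limbic))
  lo[!is.na(idx)] <- lo_limbic[idx[!is.na(idx)]]
  out$subfactor_loading <- lo
  out
}

#' Default per-region simulation parameters
#'
#' Expands the bilateral region table into the per-region specification the
#' simulator consumes: baseline volume, linear age slope (volume loss of
#' 0.25\% of baseline per year, a typical atrophy rate in mid-to-late
#' adulthood), residual noise SD, covariance-block labels and factor
#' loadings, confounder loadings (intracranial volume, scanner site,
#' surface-quality score), and a per-region direct exposure slope
#' (mm\eqn{^3} per childbirth; zero by default).
#'
#' @return A tibble with one row per bilateral region and columns
#'   `base_region`, `compartment`, `block`, `subblock`, `baseline`,
#'   `age_slope`, `noise_sd`, `exposure_slope`, `icv_loading`, `qc_loading`,
#'   `site_scale`, `block_loading`, `subfactor_loading`.
#' @export
default_region_spec <- function() {
  region_base_table() %>%
    mutate(
      age_slope = -0.0025 * .data$baseline,
      noise_sd = .data$noise_cv * .data$baseline,
      exposure_slope = 0,
      icv_loading = 0.5 * .data$baseline / 1.45e6,
      qc_loading = 3e-4 * .data$baseline,
      site_scale = 0.004 * .data$baseline,
      eth_scale = 0.003 * .data$baseline,
      block_loading = sqrt(0.15)
    ) %>%
    select("base_region", "compartment", "block", "subblock", "baseline",
           "age_slope", "noise_sd", "exposure_slope", "icv_loading",
           "qc_loading", "site_scale", "eth_scale", "block_loading",
           "subfactor_loading")
}
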