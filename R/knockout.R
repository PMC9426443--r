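## Genome-wide single-knockout phenotype scan: zero each gene's transcript
## curve, rerun the diel simulation under a fixed scenario, and compare
## final normalized biomass and composition to the wild type.

#' Simulate every single-gene knockout under a fixed scenario
#'
#' The wild type is simulated first as the control; each knockout is then a
#' pure function of (model, curves, scenario), so results are independent
#' of gene order and of how the work is distributed. Per-gene failures are
#' recorded as status entries rather than aborting the scan.
#'
#' @param bundle a scenario bundle from [diel_scenario()] (or an equivalent
#'   list with `dmodel`, `fits`, `env`, `setpoints`, `light_rule`).
#' @param genes genes to knock out (default: all genes with fitted curves
#'   that appear in the model's GPRs, plus any requested explicitly).
#' @param hours,dt simulation length (default 24-h quick mode; the
#'   full-week survey uses `hours = 168`) and timestep.
#' @param workers number of parallel workers (forked; 1 = serial).
#' @return tibble of class `knockout_scan`: `gene_id`, `status` (`grew`,
#'   `impaired`, `died`, or `error`), `normalized_mass`, `relative_to_wt`,
#'   plus final component mass fractions (`frac_*`). The first row is the
#'   wild-type control with ratio exactly 1.
#' @export
scan_knockouts <- function(bundle, genes = NULL, hours = 24, dt = 0.1,
                           workers = 1) {
  if (is.null(genes)) {
    in_gpr <- unique(unlist(lapply(bundle$dmodel$model$reactions$gpr,
                                   gpr_genes_from_string)))
    genes <- intersect(unique(bundle$fits$gene_id), in_gpr)
  }
  poss_wt <- production_possibilities(
    bundle$dmodel, bundle$fits, bundle$env,
    calibrate_umax(bundle$light_rule, build_fraction_ctx(bundle$fits),
                   bundle$env$light_availability))
  run_one <- function(fits, possibilities = NULL) {
    sim <- simulate_diel(bundle$dmodel, fits, bundle$env, bundle$setpoints,
                         hours = hours, dt = dt,
                         light_rule = bundle$light_rule,
                         possibilities = possibilities)
    fin <- sim$trajectory[nrow(sim$trajectory), ]
    mass_cols <- grep("^mass_", names(fin), value = TRUE)
    fr <- unlist(fin[mass_cols]) / fin$total
    names(fr) <- sub("^mass_", "frac_", names(fr))
    c(list(status_sim = sim$status, normalized_mass = fin$normalized),
      as.list(fr))
  }
  wt <- run_one(bundle$fits, poss_wt)
  ko_one <- function(g) {
    tryCatch({
      res <- run_one(knockout_curves(bundle$fits, g))
      ratio <- res$normalized_mass / wt$normalized_mass
      status <- if (res$status_sim == "died") "died"
      else if (ratio < 0.95) "impaired" else "grew"
      tibble::as_tibble(c(list(gene_id = g, status = status,
                               normalized_mass = res$normalized_mass,
                               relative_to_wt = ratio),
                          res[grep("^frac_", names(res))]))
    }, error = function(e) {
      tibble::tibble(gene_id = g, status = "error",
                     normalized_mass = NA_real_, relative_to_wt = NA_real_)
    })
  }
  rows <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(genes, ko_one, mc.cores = workers)
  } else {
    lapply(genes, ko_one)
  }
  wt_row <- tibble::as_tibble(c(list(gene_id = "WT",
                                     status = if (wt$status_sim == "died")
                                       "died" else "grew",
                                     normalized_mass = wt$normalized_mass,
                                     relative_to_wt = 1),
                                wt[grep("^frac_", names(wt))]))
  out <- dplyr::bind_rows(wt_row, dplyr::bind_rows(rows))
  class(out) <- c("knockout_scan", class(out))
  out
}

#' Classify and rank knockout phenotypes
#'
#' Underperformers show a growth defect at or beyond the threshold (final
#' biomass ratio at most `underperform_threshold`, default 0.75 = a 25%+
#' defect); overperformers reach at least `overperform_threshold` (default
#' 1.10 = a 10%+ biomass increase; boundaries inclusive). Both tables are
#' sorted by effect size.
#'
#' @param results a `knockout_scan` table.
#' @param underperform_threshold ratio at or below which a knockout is an
#'   underperformer.
#' @param overperform_threshold ratio at or above which a knockout is an
#'   overperformer.
#' @return list with tibbles `underperformers`, `overperformers` (the
#'   wild-type control row is excluded).
#' @export
classify_knockouts <- function(results, underperform_threshold = 0.75,
                               overperform_threshold = 1.10) {
  res <- dplyr::filter(results, .data$gene_id != "WT")
  under <- dplyr::arrange(
    dplyr::filter(res, !is.na(.data$relative_to_wt),
                  .data$relative_to_wt <= underperform_threshold |
                    .data$status == "died"),
    .data$relative_to_wt)
  over <- dplyr::arrange(
    dplyr::filter(res, !is.na(.data$relative_to_wt),
                  .data$relative_to_wt >= overperform_threshold),
    dplyr::desc(.data$relative_to_wt))
  list(underperformers = under, overperformers = over)
}
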