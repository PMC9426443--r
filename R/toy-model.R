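## A compact synthetic photoautotroph: ~30 reactions over ~26 metabolites
## and ~25 genes, exercising light harvesting, carbon fixation, respiration
## in a mitochondrial ATP pseudo-compartment with a plastid/mito ATP
## translocator, starch storage and night catabolism, acetate assimilation,
## and synthesis routes to all ten biomass component pools, each under a
## GPR over the synthetic gene set. Every internal reaction is elementally
## balanced (components are built from CH2O and NH3 units; ATP/NADP
## cofactors use consistent formulas). The fixture is a test harness, not a
## biological claim.

toy_metabolites <- function() {
  tibble::tribble(
    ~id,        ~formula,          ~compartment,
    "photon",   "",                "e",
    "co2",      "CO2",             "c",
    "ac",       "C2H4O2",          "c",
    "nh3",      "H3N",             "c",
    "o2",       "O2",              "c",
    "h2o",      "H2O",             "c",
    "h",        "H",               "c",
    "pi",       "H3O4P",           "c",
    "adp",      "C10H15N5O10P2",   "c",
    "atp_p",    "C10H16N5O13P3",   "p",
    "atp_m",    "C10H16N5O13P3",   "m",
    "nadp",     "C21H28N7O17P3",   "p",
    "nadph",    "C21H29N7O17P3",   "p",
    "ch2o",     "CH2O",            "c",
    "caro_m",   "C20H40O20",       "c",
    "chla_m",   "C30H72N4O30",     "p",
    "chlb_m",   "C30H72N4O30",     "p",
    "prot_m",   "C4H11NO4",        "c",
    "lip_m",    "C10H23NO10",      "c",
    "tag1_m",   "C12H24O12",       "c",
    "tag2_m",   "C12H24O12",       "c",
    "carb_m",   "C6H12O6",         "c",
    "nuc_m",    "C5H16N2O5",       "c",
    "redox_m",  "C15H45N5O15",     "c",
    "starch_m", "C6H12O6",         "p")
}

## component synthesis: n_c CH2O + n_n NH3 + n_a ATP(p) (+ n_a H2O) ->
## component + n_a ADP + n_a Pi; elementally balanced by construction
toy_synthesis <- function(id, product, n_c, n_n, n_a, gpr) {
  mets <- c(ch2o = -n_c, atp_p = -n_a, h2o = -n_a,
            adp = n_a, pi = n_a)
  if (n_n > 0) mets <- c(mets, nh3 = -n_n)
  mets[product] <- 1
  list(id = id, mets = mets, gpr = gpr, lb = 0, ub = 1000, obj = 0)
}

toy_reference_composition <- function() {
  c(carotenoid = 0.01, chlorophyll_a = 0.02, chlorophyll_b = 0.01,
    protein = 0.45, lipid = 0.12, lipid_droplet = 0.03,
    carbohydrate = 0.12, nucleotide = 0.06, redox = 0.03, starch = 0.15)
}

#' Diel biomass-composition setpoint table for the toy model
#'
#' Starch rises from 0.15 at dawn to 0.30 at dusk and is burned back down
#' overnight; protein and carbohydrate make room for it during the day.
#' Fractions sum to exactly 1 at each tabulated time (intermediate times
#' are linear interpolations, so their sums are 1 as well).
#'
#' @return tibble `time`, `component`, `fraction`.
#' @export
toy_setpoints <- function() {
  ref <- toy_reference_composition()
  dusk <- ref
  dusk["starch"] <- 0.30
  dusk["protein"] <- 0.35
  dusk["carbohydrate"] <- 0.07
  purrr::map_dfr(names(ref), function(k) {
    tibble::tibble(time = c(0, 12, 24), component = k,
                   fraction = c(ref[[k]], dusk[[k]], ref[[k]]))
  })
}

toy_gene_curves <- function() {
  tibble::tribble(
    ~gene_id, ~family,           ~params,
    "gLHC1",  "one_term_cosine", c(c = 100, A = 80, phi = 6),
    "gPSB1",  "one_term_cosine", c(c = 120, A = 60, phi = 5),
    "gPSA1",  "one_term_cosine", c(c = 110, A = 70, phi = 6),
    "gRBC1",  "one_term_cosine", c(c = 90, A = 60, phi = 5),
    "gRBC2",  "two_term_cosine", c(c = 90, A1 = 50, phi1 = 5, A2 = 15, phi2 = 2),
    "gCOX1",  "constant",        c(c = 80),
    "gAAC1",  "constant",        c(c = 60),
    "gACS1",  "constant",        c(c = 70),
    "gCARO1", "one_term_cosine", c(c = 60, A = 30, phi = 4),
    "gCHL1",  "one_term_cosine", c(c = 80, A = 50, phi = 5),
    "gCHL2",  "constant",        c(c = 50),
    "gCHL3",  "constant",        c(c = 40),
    "gPRT1",  "constant",        c(c = 100),
    "gPRT2",  "one_term_cosine", c(c = 50, A = 30, phi = 8),
    "gLIP1",  "constant",        c(c = 90),
    "gTAG1",  "one_term_cosine", c(c = 70, A = 40, phi = 10),
    "gTAG2",  "constant",        c(c = 30),
    "gCRB1",  "constant",        c(c = 85),
    "gNUC1",  "one_term_cosine", c(c = 60, A = 30, phi = 2),
    "gRDX1",  "constant",        c(c = 45),
    "gSTA6",  "one_term_cosine", c(c = 80, A = 60, phi = 6),
    "gAMY1",  "one_term_cosine", c(c = 70, A = 40, phi = 18),
    "gORPH1", "constant",        c(c = 55),
    "gFLA1",  "one_term_cosine", c(c = 40, A = 30, phi = 18),
    "gSTR1",  "kronecker_delta", c(c = 20, A = 200, t0 = 0, width = 2))
}

#' Build a `diel_fits` table directly from known family parameters
#'
#' Constructs per-gene ensembles with weight 1 on the stated family and
#' weight 0 elsewhere, bypassing the fitting step. Used by the synthetic
#' fixtures, where generating curves are known exactly.
#'
#' @param curves tibble `gene_id`, `family`, `params` (list column).
#' @return a `diel_fits` tibble.
#' @export
analytic_fits <- function(curves) {
  fams <- expression_families()
  out <- purrr::map_dfr(seq_len(nrow(curves)), function(i) {
    g <- curves$gene_id[i]; fam <- curves$family[i]
    tibble::tibble(
      gene_id = g, family = fams,
      params = lapply(fams, function(f) {
        if (f == fam) curves$params[[i]] else NULL
      }),
      n_params = vapply(fams, function(f) get_family(f)$n_params, 1L),
      rss = ifelse(fams == fam, 0, NA_real_),
      aicc = ifelse(fams == fam, 0, Inf),
      n_obs = 13L,
      weight = as.numeric(fams == fam),
      best = fams == fam)
  })
  class(out) <- c("diel_fits", class(out))
  attr(out, "period") <- 24
  attr(out, "families") <- fams
  out
}

#' Build the synthetic toy photoautotroph fixture
#'
#' Returns the base model (with a single biomass equation over the ten
#' component metabolite pools), a matched transcript curve set (weight-1
#' analytic ensembles whose light-harvesting genes peak midday), a sampled
#' synthetic expression table, the diel setpoint table, and the
#' metabolite-to-component map. The designated starch-synthesis gene
#' (`gSTA6`) is the sole gene of the starch synthesis reaction, so its
#' knockout removes starch storage entirely.
#'
#' @param include_acetate include the acetate exchange/assimilation route.
#' @param noise_cv multiplicative noise applied when sampling the bundled
#'   expression table (the curve set itself is exact).
#' @param seed seed for expression sampling.
#' @return list: `model`, `fits`, `expression`, `setpoints`,
#'   `component_map`, `tag_list`, `gene_curves`, `light_rule`.
#' @export
#' @examples
#' toy <- build_toy_model()
#' toy$model
build_toy_model <- function(include_acetate = TRUE, noise_cv = 0, seed = 1) {
  mets <- toy_metabolites()
  mw <- stats::setNames(formula_weight(mets$formula), mets$id)
  comp_mets <- c(carotenoid = "caro_m", chlorophyll_a = "chla_m",
                 chlorophyll_b = "chlb_m", protein = "prot_m",
                 lipid = "lip_m", carbohydrate = "carb_m",
                 nucleotide = "nuc_m", redox = "redox_m",
                 starch = "starch_m")
  ref <- toy_reference_composition()
  ## biomass coefficients, mmol per gDW (droplet split evenly over 2 TAGs)
  bio <- c()
  for (k in names(comp_mets)) {
    m <- comp_mets[[k]]
    bio[m] <- -1000 * ref[[k]] / mw[[m]]
  }
  bio["tag1_m"] <- -1000 * ref[["lipid_droplet"]] / 2 / mw[["tag1_m"]]
  bio["tag2_m"] <- -1000 * ref[["lipid_droplet"]] / 2 / mw[["tag2_m"]]

  rxns <- list(
    list(id = "EX_photon", mets = c(photon = -1), gpr = "", lb = -20, ub = 1000, obj = 0),
    list(id = "EX_co2", mets = c(co2 = -1), gpr = "", lb = -10, ub = 1000, obj = 0),
    list(id = "EX_nh3", mets = c(nh3 = -1), gpr = "", lb = -5, ub = 1000, obj = 0),
    list(id = "EX_o2", mets = c(o2 = -1), gpr = "", lb = -1000, ub = 1000, obj = 0),
    list(id = "EX_h2o", mets = c(h2o = -1), gpr = "", lb = -1000, ub = 1000, obj = 0),
    list(id = "EX_h", mets = c(h = -1), gpr = "", lb = -1000, ub = 1000, obj = 0),
    list(id = "LHC", mets = c(photon = -1, adp = -1, pi = -1, atp_p = 1, h2o = 1),
         gpr = "gLHC1 and gPSB1", lb = 0, ub = 1000, obj = 0),
    list(id = "PSN", mets = c(photon = -1, nadp = -1, h2o = -1,
                              nadph = 1, h = 1, o2 = 0.5),
         gpr = "gPSA1", lb = 0, ub = 1000, obj = 0),
    list(id = "CBB", mets = c(co2 = -1, nadph = -2, h = -2, atp_p = -3,
                              h2o = -2, ch2o = 1, nadp = 2, adp = 3, pi = 3),
         gpr = "gRBC1 and gRBC2", lb = 0, ub = 1000, obj = 0),
    list(id = "RESP", mets = c(ch2o = -1, o2 = -1, adp = -2, pi = -2,
                               co2 = 1, h2o = 3, atp_m = 2),
         gpr = "gCOX1", lb = 0, ub = 1000, obj = 0),
    list(id = "ATPT", mets = c(atp_p = -1, atp_m = 1),
         gpr = "gAAC1", lb = -1000, ub = 1000, obj = 0),
    list(id = "NGAM", mets = c(atp_m = -1, h2o = -1, adp = 1, pi = 1),
         gpr = "", lb = 0, ub = 1000, obj = 0),
    toy_synthesis("CAROS", "caro_m", 20, 0, 5, "gCARO1"),
    toy_synthesis("CHLAS", "chla_m", 30, 4, 8, "gCHL1 and gCHL2"),
    toy_synthesis("CHLBS", "chlb_m", 30, 4, 8, "gCHL1 and gCHL3"),
    toy_synthesis("PROTS", "prot_m", 4, 1, 4, "gPRT1 or gPRT2"),
    toy_synthesis("LIPS", "lip_m", 10, 1, 6, "gLIP1"),
    toy_synthesis("TAG1S", "tag1_m", 12, 0, 7, "gTAG1"),
    toy_synthesis("TAG2S", "tag2_m", 12, 0, 7, "gTAG1 or gTAG2"),
    toy_synthesis("CARBS", "carb_m", 6, 0, 2, "gCRB1"),
    toy_synthesis("NUCS", "nuc_m", 5, 2, 10, "gNUC1"),
    toy_synthesis("REDOXS", "redox_m", 15, 5, 20, "gRDX1"),
    toy_synthesis("STAS", "starch_m", 6, 0, 2, "gSTA6"),
    list(id = "STARCH_DEG", mets = c(starch_m = -1, ch2o = 6),
         gpr = "gAMY1", lb = 0, ub = 1000, obj = 0),
    list(id = "BIOMASS", mets = bio, gpr = "", lb = 0, ub = 1000, obj = 1)
  )
  if (include_acetate) {
    rxns <- c(rxns, list(
      list(id = "EX_ac", mets = c(ac = -1), gpr = "", lb = 0, ub = 1000, obj = 0),
      list(id = "ACS", mets = c(ac = -1, atp_m = -1, h2o = -1,
                                ch2o = 2, adp = 1, pi = 1),
           gpr = "gACS1", lb = 0, ub = 1000, obj = 0)))
  }
  rxn_tbl <- purrr::map_dfr(rxns, function(r) {
    tibble::tibble(id = r$id, name = r$id, lb = r$lb, ub = r$ub,
                   gpr = r$gpr, objective = r$obj)
  })
  S <- matrix(0, nrow(mets), length(rxns),
              dimnames = list(mets$id, rxn_tbl$id))
  for (j in seq_along(rxns)) S[names(rxns[[j]]$mets), j] <- rxns[[j]]$mets

  curves <- toy_gene_curves()
  model <- metabolic_model("toy_photoautotroph", mets, rxn_tbl, S,
                           genes = curves$gene_id)
  fits <- analytic_fits(curves)

  ## sampled expression table matching the curve set (2-h diel sampling)
  ts <- seq(0, 24, by = 2)
  sdlog <- sqrt(log(1 + noise_cv^2))
  expression <- withr::with_seed(seed, purrr::map_dfr(
    seq_len(nrow(curves)), function(i) {
      mu <- pmax(eval_family(curves$family[i], curves$params[[i]], ts), 0)
      noise <- if (noise_cv > 0) exp(stats::rnorm(length(mu), -sdlog^2 / 2, sdlog))
      else rep(1, length(mu))
      tibble::tibble(gene_id = curves$gene_id[i], time = ts,
                     fpkm = pmax(mu * noise, 0))
    }))

  tag_list <- c("tag1_m", "tag2_m")
  lipid_species <- c("lip_m", tag_list)
  component_map <- dplyr::bind_rows(
    tibble::tibble(metabolite = unname(comp_mets),
                   component = names(comp_mets)),
    split_lipids(lipid_species, tag_list)[
      split_lipids(lipid_species, tag_list)$metabolite %in% tag_list, ])
  list(model = model, fits = fits, expression = expression,
       setpoints = toy_setpoints(), component_map = component_map,
       tag_list = tag_list, gene_curves = curves,
       light_rule = "gLHC1 and gPSB1")
}

#' Named diel growth scenarios on the toy fixture
#'
#' Reproducible input bundles for the qualitative phenotype experiments:
#' wild type and the starchless (sta6-like) knockout, each on minimal
#' (CO2-only) or acetate medium, plus a nitrogen-limitation series with
#' monotonically decreasing ammonium uptake bounds.
#'
#' @param name one of `"wt_minimal"`, `"wt_acetate"`, `"sta6_minimal"`,
#'   `"sta6_acetate"`, `"n_limited_series"`.
#' @param light_availability photon uptake ceiling during the photoperiod
#'   (mmol/gDW/h); the default produces roughly one doubling per day for
#'   the wild type.
#' @param ngam maintenance ATP demand (mmol/gDW/h).
#' @param seed seed recorded in the bundle.
#' @return a scenario bundle: list with `name`, `model`, `dmodel`
#'   (decoupled), `fits`, `env`, `setpoints`, `light_rule`, `seed`; for
#'   `"n_limited_series"`, a list of bundles with decreasing nitrogen.
#' @export
diel_scenario <- function(name = c("wt_minimal", "wt_acetate", "sta6_minimal",
                                   "sta6_acetate", "n_limited_series"),
                          light_availability = 15.6, ngam = 1.2, seed = 1) {
  name <- match.arg(name)
  toy <- build_toy_model(include_acetate = TRUE, seed = seed)
  dmodel <- split_biomass(toy$model, toy$component_map)
  base_medium <- c(EX_co2 = 10, EX_nh3 = 5, EX_o2 = 1000, EX_h2o = 1000,
                   EX_h = 1000)
  make_env <- function(medium) {
    diel_environment(light_availability, medium = medium, ngam = ngam,
                     ngam_reaction = "NGAM", light_exchange = "EX_photon")
  }
  bundle <- function(nm, fits, medium) {
    list(name = nm, model = toy$model, dmodel = dmodel, fits = fits,
         env = make_env(medium), setpoints = toy$setpoints,
         light_rule = toy$light_rule, seed = seed)
  }
  ko <- function() knockout_curves(toy$fits, "gSTA6")
  switch(name,
    wt_minimal = bundle("wt_minimal", toy$fits, base_medium),
    wt_acetate = bundle("wt_acetate", toy$fits, c(base_medium, EX_ac = 2)),
    sta6_minimal = bundle("sta6_minimal", ko(), base_medium),
    sta6_acetate = bundle("sta6_acetate", ko(), c(base_medium, EX_ac = 2)),
    n_limited_series = {
      nh3_levels <- c(5, 2, 1, 0.5, 0.2)
      lapply(nh3_levels, function(nl) {
        med <- base_medium; med["EX_nh3"] <- nl
        b <- bundle(paste0("wt_n", nl), toy$fits, med)
        b$nh3 <- nl
        b
      })
    })
}

#' Run a scenario bundle end to end
#'
#' @param bundle a scenario bundle from [diel_scenario()].
#' @param hours,dt simulation length and timestep.
#' @param ... passed to [simulate_diel()].
#' @return a `diel_simulation`.
#' @export
run_scenario <- function(bundle, hours = 24, dt = 0.1, ...) {
  simulate_diel(bundle$dmodel, bundle$fits, bundle$env, bundle$setpoints,
                hours = hours, dt = dt, light_rule = bundle$light_rule, ...)
}
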