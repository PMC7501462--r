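# Seeded generators for every input the pipeline needs: a toy genome-scale
# model of a polyketide-producing actinomycete (glycolysis, pentose
# phosphate pathway, TCA cycle, oxidative phosphorylation, fatty-acid
# biosynthesis, four deletable biosynthetic-gene-cluster pathways and a
# germicidin-analog pathway present in all strains), thermodynamic and kcat
# tables with planted directionality, batch-fermentation time series with
# strain-specific growth rates and phosphate-depletion times, a
# demand-proportional proteome with a pre/post-switch allocation shift, and
# phenotype tests with a planted confusion structure.

#' Configuration of the synthetic study
#'
#' The strain presets plant the published physiology of the M145-like
#' producer and its cluster-deletion mutants: growth rates 0.21 / 0.21 /
#' 0.15 1/h, phosphate depletion at 35 / 38 / 47 h, and germicidin-analog
#' production scale factors 1 / 0.73 / 0.08 (A) and 1 / 0.75 / 0.18 (B) for
#' M145 / M1146 / M1152 (back-calculated from the reported 27/25% and
#' 92/82% production reductions).
#'
#' @param seed integer master seed; all generators derive their streams
#'   from it.
#' @param noise_sd relative (multiplicative Gaussian) noise on time-series
#'   measurements; 0 gives noise-free series.
#' @param ... named overrides of individual config fields.
#' @return a `toy_config` list.
#' @export
toy_config <- function(seed = 1L, noise_sd = 0.02, ...) {
  cfg <- list(
    seed = as.integer(seed),
    noise_sd = noise_sd,
    strains = list(
      M145 = list(mu = 0.21, t_depletion = 35,
                   germ_scale = c(A = 1.00, B = 1.00),
                   n_glc = 0.8, n_glu = 1.05, bgc = TRUE),
      M1146 = list(mu = 0.21, t_depletion = 38,
                    germ_scale = c(A = 0.73, B = 0.75),
                    n_glc = 0.8, n_glu = 1.05, bgc = FALSE),
      M1152 = list(mu = 0.15, t_depletion = 47,
                    germ_scale = c(A = 0.08, B = 0.18),
                    n_glc = 0.62, n_glu = 1.3, bgc = FALSE)),
    grid = seq(0, 72, by = 1),          # hourly sampling, h
    x0 = 0.002,                         # inoculum, g/L
    pi0 = 1.0,                          # phosphate, mmol/L
    glc0 = 60, glu0 = 55,               # substrates, mmol/L
    m_glc = 0.15, m_glu = 0.15,         # post-switch maintenance, mmol/gDW/h
    q_germ = c(A = 0.9, B = 0.6),       # germicidin analogs, mg/gDW/h
    bgc_products = list(                # onset after depletion (h), mg/gDW/h
      act = c(onset = 6, rate = 2.0), red = c(onset = 2, rate = 1.5),
      cda = c(onset = 2, rate = 0.8), cpk = c(onset = -5, rate = 0.4)),
    co2_pre = 30,                       # mmol CO2 per g biomass formed
    co2_post = 3.8,                     # mmol/gDW/h post switch
    uptake_glc = 10, uptake_glu = 6,    # reference-medium bounds, mmol/gDW/h
    uptake_pi = 0.2, biomass_pi = 0.5,  # planted mu_max = 0.2 / 0.5 = 0.4
    thermo_sd = 5,                      # kJ/mol noise on delta-G
    thermo_mean = 45,                   # |mean| of planted irreversible dG
    kcat_median = 3600, kcat_sdlog = 0.3,
    mw_range = c(20, 50),               # g/mmol
    proteome = list(
      offsets = c(-6, -3, -1, 1, 3, 5, 7, 9),  # h relative to depletion
      headroom = 2, noise_sdlog = 0.1, withheld_fraction = 0.1,
      transition_h = 1.5,
      post_factor = c("Oxidative phosphorylation" = 1.8,
                      "Fatty acid biosynthesis" = 0.3,
                      "Glycolysis" = 0.6, "TCA cycle" = 1.2,
                      "Amino acid metabolism" = 0.7),
      bgc_capacity = c(pre = 2.2e-3, post = 3e-3),   # synthase flux scale
      germ_capacity = c(pre = 0.002, post = 0.006),
      # planted overcapacity at precursor-supply nodes (NADPH, malonyl-CoA,
      # acetyl-CoA), emulating the reserve capacity of central metabolism
      capacity_boost = c(G6PDH = 3, RPI = 3, TKT = 3, ACC = 3, PDH = 2,
                         AASYN = 1.5, GS = 1.5, PPC = 2, PCK = 2),
      floor_capacity = 0.003),
    phenotype = list(n_growth = 197, n_nogrowth = 44,
                     flip_growth = 42, flip_nogrowth = 6),
    pool = pool_params())
  override <- list(...)
  cfg[names(override)] <- override
  structure(cfg, class = "toy_config")
}

toy_metabolites <- function() {
  cmet <- function(id, formula = "") tibble(id = id, name = id,
                                            compartment = "c",
                                            formula = formula,
                                            charge = NA_integer_)
  emet <- function(id, formula = "") tibble(id = id, name = id,
                                            compartment = "e",
                                            formula = formula,
                                            charge = NA_integer_)
  bind_rows(
    emet("glc_e", "C6"), emet("glu_e", "C5"), emet("pi_e"), emet("nh4_e"),
    emet("ac_e", "C2"), emet("co2_e", "C1"), emet("o2_e"),
    emet("act_e"), emet("red_e"), emet("cda_e"), emet("cpk_e"),
    emet("germA_e"), emet("germB_e"),
    cmet("glc_c", "C6"), cmet("g6p_c", "C6"), cmet("f6p_c", "C6"),
    cmet("g3p_c", "C3"), cmet("pep_c", "C3"), cmet("pyr_c", "C3"),
    cmet("accoa_c", "C2"), cmet("malcoa_c", "C3"), cmet("akg_c", "C5"),
    cmet("oaa_c", "C4"), cmet("glu_c", "C5"), cmet("gln_c", "C5"),
    cmet("aa_c", "C3"), cmet("ru5p_c", "C5"), cmet("r5p_c", "C5"),
    cmet("fa_c", "C16"), cmet("lipid_c", "C16"), cmet("ac_c", "C2"),
    cmet("co2_c", "C1"), cmet("o2_c"), cmet("nh4_c"), cmet("pi_c"),
    cmet("atp_c"), cmet("adp_c"), cmet("amp_c"),
    cmet("nad_c"), cmet("nadh_c"), cmet("nadp_c"), cmet("nadph_c"),
    cmet("fad_c"), cmet("fadh2_c"), cmet("pmf_c"),
    cmet("act_c"), cmet("red_c"), cmet("cda_c"), cmet("cpk_c"),
    cmet("germA_c"), cmet("germB_c"))
}

toy_reactions <- function(config) {
  B <- default_bound()
  rx <- function(id, stoich, lb, ub, gene = "", subsystem = "",
                 pathway = subsystem) {
    tibble(id = id, stoichiometry = list(stoich), lb = lb, ub = ub,
           gene_rule = gene, subsystem = subsystem, pathway = pathway)
  }
  ex <- function(id, met, lb = 0, ub = B) {
    rx(id, setNames(-1, met), lb, ub, subsystem = "Exchange")
  }
  bind_rows(
    ex("EX_glc", "glc_e", -config$uptake_glc),
    ex("EX_glu", "glu_e", -config$uptake_glu),
    ex("EX_pi", "pi_e", -config$uptake_pi),
    ex("EX_nh4", "nh4_e", -10, B),
    ex("EX_o2", "o2_e", -B),
    ex("EX_co2", "co2_e"), ex("EX_ac", "ac_e"),
    ex("EX_act", "act_e"), ex("EX_red", "red_e"),
    ex("EX_cda", "cda_e"), ex("EX_cpk", "cpk_e"),
    ex("EX_germA", "germA_e"), ex("EX_germB", "germB_e"),

    rx("GLCt", c(glc_e = -1, glc_c = 1), 0, B, "gGLCt", "Transport"),
    rx("GLUt", c(glu_e = -1, glu_c = 1), 0, B, "gGLUt", "Transport"),
    rx("PIt", c(pi_e = -1, pi_c = 1), 0, B, "gPIt", "Transport"),
    rx("NH4t", c(nh4_e = -1, nh4_c = 1), -B, B, "gNH4t", "Transport"),
    rx("O2t", c(o2_e = -1, o2_c = 1), 0, B, "", "Transport"),
    rx("CO2t", c(co2_c = -1, co2_e = 1), -B, B, "", "Transport"),
    rx("ACt", c(ac_c = -1, ac_e = 1), 0, B, "", "Transport"),
    rx("ACTt", c(act_c = -1, act_e = 1), 0, B, "", "Transport"),
    rx("REDt", c(red_c = -1, red_e = 1), 0, B, "", "Transport"),
    rx("CDAt", c(cda_c = -1, cda_e = 1), 0, B, "", "Transport"),
    rx("CPKt", c(cpk_c = -1, cpk_e = 1), 0, B, "", "Transport"),
    rx("GERMAt", c(germA_c = -1, germA_e = 1), 0, B, "", "Transport"),
    rx("GERMBt", c(germB_c = -1, germB_e = 1), 0, B, "", "Transport"),

    rx("HEX1", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1), 0, B,
       "gHEX1", "Glycolysis"),
    rx("PGI", c(g6p_c = -1, f6p_c = 1), -B, B, "gPGI1 or gPGI2",
       "Glycolysis"),
    rx("PFK", c(f6p_c = -1, atp_c = -1, adp_c = 1, g3p_c = 2), 0, B,
       "gPFK", "Glycolysis"),
    rx("GAPD", c(g3p_c = -1, nad_c = -1, adp_c = -1, pep_c = 1,
                 nadh_c = 1, atp_c = 1), -B, B, "gGAPD", "Glycolysis"),
    rx("PYK", c(pep_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1), 0, B,
       "gPYK", "Glycolysis"),

    rx("G6PDH", c(g6p_c = -1, nadp_c = -2, ru5p_c = 1, co2_c = 1,
                  nadph_c = 2), 0, B, "gG6PDH", "Pentose phosphate pathway"),
    rx("RPI", c(ru5p_c = -1, r5p_c = 1), -B, B, "gRPI",
       "Pentose phosphate pathway"),
    rx("TKT", c(ru5p_c = -3, f6p_c = 2, g3p_c = 1), -B, B, "gTKT",
       "Pentose phosphate pathway"),

    rx("PDH", c(pyr_c = -1, nad_c = -1, accoa_c = 1, co2_c = 1,
                nadh_c = 1), 0, B, "gPDH", "TCA cycle"),
    rx("CS", c(accoa_c = -1, oaa_c = -1, nad_c = -1, akg_c = 1,
               co2_c = 1, nadh_c = 1), 0, B, "gCS", "TCA cycle"),
    rx("AKGDH", c(akg_c = -1, nad_c = -2, fad_c = -1, adp_c = -1,
                  oaa_c = 1, co2_c = 1, nadh_c = 2, fadh2_c = 1,
                  atp_c = 1), 0, B, "gAKGDH", "TCA cycle"),
    rx("PPC", c(pep_c = -1, co2_c = -1, oaa_c = 1), 0, B, "gPPC",
       "TCA cycle", "Anaplerosis"),
    rx("PCK", c(oaa_c = -1, atp_c = -1, pep_c = 1, co2_c = 1,
                adp_c = 1), 0, B, "gPCK", "TCA cycle", "Anaplerosis"),

    rx("GLUDH", c(glu_c = -1, nad_c = -1, akg_c = 1, nh4_c = 1,
                  nadh_c = 1), -B, B, "gGLUDH", "Amino acid metabolism"),
    rx("AASYN", c(pyr_c = -1, glu_c = -1, atp_c = -1, aa_c = 1,
                  akg_c = 1, adp_c = 1), 0, B, "gAASYN",
       "Amino acid metabolism"),
    rx("GS", c(glu_c = -1, nh4_c = -1, atp_c = -1, gln_c = 1,
               adp_c = 1), -B, B, "gGS", "Amino acid metabolism"),

    rx("NADHDH", c(nadh_c = -1, o2_c = -0.5, nad_c = 1, pmf_c = 3),
       0, B, "gNUO", "Oxidative phosphorylation"),
    rx("FADHDH", c(fadh2_c = -1, o2_c = -0.5, fad_c = 1, pmf_c = 2),
       0, B, "gSDH", "Oxidative phosphorylation"),
    rx("ATPS", c(pmf_c = -3, adp_c = -1, atp_c = 1), -B, B, "gATPS",
       "Oxidative phosphorylation"),

    rx("ATPM", c(atp_c = -1, adp_c = 1), 0, B, "", "Maintenance"),
    rx("ADK", c(atp_c = -1, amp_c = -1, adp_c = 2), -B, B, "gADK",
       "Maintenance"),
    rx("PTA_ACK", c(accoa_c = -1, adp_c = -1, ac_c = 1, atp_c = 1),
       0, B, "gPTA", "Overflow metabolism"),

    rx("ACC", c(accoa_c = -1, atp_c = -1, co2_c = -1, malcoa_c = 1,
                adp_c = 1), 0, B, "gACC", "Malonyl-CoA metabolism"),
    rx("FAS", c(accoa_c = -1, malcoa_c = -7, nadph_c = -14, fa_c = 1,
                co2_c = 7, nadp_c = 14), 0, B, "gFASa and gFASb",
       "Fatty acid biosynthesis"),
    rx("LIPSYN", c(fa_c = -1, atp_c = -1, lipid_c = 1, adp_c = 1), 0, B,
       "gLIP", "Fatty acid biosynthesis"),

    rx("ACTS", c(malcoa_c = -8, nadph_c = -4, act_c = 1, co2_c = 8,
                 nadp_c = 4), 0, B, "gACTa and gACTb", "Act biosynthesis"),
    rx("REDS", c(malcoa_c = -4, aa_c = -2, nadph_c = -2, red_c = 1,
                 co2_c = 4, nadp_c = 2), 0, B, "gRED", "Red biosynthesis"),
    rx("CDAS", c(aa_c = -3, malcoa_c = -2, atp_c = -1, cda_c = 1,
                 co2_c = 2, adp_c = 1), 0, B, "gCDA", "Cda biosynthesis"),
    rx("CPKS", c(malcoa_c = -5, nadph_c = -2, cpk_c = 1, co2_c = 5,
                 nadp_c = 2), 0, B, "gCPK", "Cpk biosynthesis"),

    rx("GERMAS", c(accoa_c = -1, malcoa_c = -2, nadph_c = -1,
                   germA_c = 1, co2_c = 2, nadp_c = 1), 0, B, "gGCS",
       "Germicidin biosynthesis"),
    rx("GERMBS", c(accoa_c = -1, malcoa_c = -2, germB_c = 1, co2_c = 2),
       0, B, "gGCS", "Germicidin biosynthesis"),

    rx("BIOMASS",
       c(aa_c = -0.9, lipid_c = -0.05, r5p_c = -0.1, g6p_c = -0.1,
         gln_c = -0.05, atp_c = -6, pi_c = -config$biomass_pi,
         adp_c = 6), 0, B, "", "Biomass"))
}

bgc_ids <- function() {
  list(reactions = c("ACTS", "REDS", "CDAS", "CPKS",
                     "ACTt", "REDt", "CDAt", "CPKt",
                     "EX_act", "EX_red", "EX_cda", "EX_cpk"),
       metabolites = c("act_c", "red_c", "cda_c", "cpk_c",
                       "act_e", "red_e", "cda_e", "cpk_e"))
}

#' Build the toy genome-scale model
#'
#' Deterministic given `(config, variant)`. The M1146/M1152 variants lack
#' the four cluster pathways (a structural deletion of reactions,
#' transporters, exchanges and their metabolites); the germicidin-analog
#' pathway is present in every variant, and growth requires phosphate. On
#' the reference medium the maximal growth rate is phosphate-limited and
#' equals `uptake_pi / biomass_pi` (0.4 1/h with defaults) by construction.
#'
#' @param config a [toy_config()].
#' @param variant `"M145"`, `"M1146"` or `"M1152"`.
#' @return a `metabolic_model`.
#' @export
build_toy_gem <- function(config = toy_config(),
                          variant = c("M145", "M1146", "M1152")) {
  variant <- match.arg(variant)
  mets <- toy_metabolites()
  rxns <- toy_reactions(config)
  if (!config$strains[[variant]]$bgc) {
    drop <- bgc_ids()
    rxns <- filter(rxns, !.data$id %in% drop$reactions)
    mets <- filter(mets, !.data$id %in% drop$metabolites)
  }
  metabolic_model(mets, rxns, objective = "BIOMASS")
}

#' Planted directionality, kcat and protein tables for the toy model
#'
#' Every internal (non-exchange, non-transport) reaction gets a planted
#' true directionality; its Gibbs-energy estimate is drawn at the
#' planted-consistent mean (-45, 0 or +45 kJ/mol) plus Normal(0, sd) noise.
#' kcats are log-normal with median 3600 1/h; one protein per gene with
#' molecular weights in 25-65 g/mmol.
#'
#' @param model a toy `metabolic_model`.
#' @param config a [toy_config()].
#' @return list with `thermo` (reaction_id, delta_g, uncertainty,
#'   planted_direction), `kcats`, `proteins` tibbles.
#' @export
make_thermo_kcats <- function(model, config = toy_config()) {
  set.seed(config$seed + 101L)
  reversible_truth <- c("PGI", "RPI", "TKT", "CO2t", "ATPS", "ADK")
  internal <- filter(model$reactions,
                     !.data$subsystem %in% c("Exchange", "Transport") |
                       .data$id == "CO2t")
  planted <- ifelse(internal$id %in% reversible_truth, "reversible", "forward")
  mu_dg <- ifelse(planted == "forward", -config$thermo_mean, 0)
  thermo <- tibble(reaction_id = internal$id,
                   delta_g = mu_dg + rnorm(nrow(internal), 0, config$thermo_sd),
                   uncertainty = config$thermo_sd,
                   planted_direction = planted)

  genes <- model$genes
  proteins <- tibble(protein_id = paste0("P_", sub("^g", "", genes)),
                     gene_id = genes,
                     mw = round(runif(length(genes), config$mw_range[1],
                                      config$mw_range[2]), 1))
  protein_of <- setNames(proteins$protein_id, proteins$gene_id)
  rows <- list()
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    if (!nzchar(r$gene_rule)) next
    dirs <- if (r$lb < 0 && r$ub > 0) c("forward", "backward") else "forward"
    for (g in gene_rule_genes(r$gene_rule)) {
      for (d in dirs) {
        rows[[length(rows) + 1]] <- tibble(
          protein_id = protein_of[[g]], reaction_id = r$id, direction = d,
          kcat = rlnorm(1, log(config$kcat_median), config$kcat_sdlog),
          match_level = "exact")
      }
    }
  }
  list(thermo = thermo, kcats = bind_rows(rows), proteins = proteins)
}

#' Synthetic batch-fermentation time series
#'
#' Exponential growth at the strain preset rate until the preset phosphate
#' depletion time, then growth arrest; phosphate declines linearly to zero
#' at depletion; glucose and glutamate are co-consumed with preset
#' mmol-per-gram yields plus post-switch maintenance; cluster products
#' appear only after depletion and only in the producer strain; germicidin
#' analogs appear post-depletion in all strains, scaled by the preset
#' factors applied to the biomass-normalized production. Multiplicative
#' Gaussian noise at `config$noise_sd`; seeded and reproducible.
#'
#' @param config a [toy_config()].
#' @param strain strain preset name.
#' @return a [cultivation_ts()] with columns `glucose`, `glutamate`,
#'   `phosphate`, `germA`, `germB`, `act`, `red`, `cda`, `cpk`.
#' @export
make_timeseries <- function(config = toy_config(), strain = "M145") {
  ps <- config$strains[[strain]]
  if (is.null(ps)) {
    abort(paste0("no preset for strain '", strain, "'"),
          class = "switchflux_usage_error")
  }
  t <- config$grid
  td <- ps$t_depletion
  x <- config$x0 * exp(ps$mu * pmin(t, td))
  x_arr <- config$x0 * exp(ps$mu * td)
  phosphate <- config$pi0 * pmax(0, 1 - t / td)
  post <- pmax(0, t - td)
  glucose <- config$glc0 - ps$n_glc * (x - config$x0) -
    config$m_glc * x_arr * post
  glutamate <- config$glu0 - ps$n_glu * (x - config$x0) -
    config$m_glu * x_arr * post
  germA <- ps$germ_scale[["A"]] * config$q_germ[["A"]] * post * x
  germB <- ps$germ_scale[["B"]] * config$q_germ[["B"]] * post * x
  bgc <- lapply(config$bgc_products, function(p) {
    if (!ps$bgc) return(rep(0, length(t)))
    p[["rate"]] * pmax(0, t - (td + p[["onset"]])) * x
  })
  co2 <- ifelse(t < td, config$co2_pre * ps$mu * x, config$co2_post * x_arr)
  out <- tibble(strain = strain, replicate = 1L, time_h = t, cdw = x,
                co2 = co2, glucose = glucose, glutamate = glutamate,
                phosphate = phosphate, germA = germA, germB = germB,
                act = bgc$act, red = bgc$red, cda = bgc$cda, cpk = bgc$cpk)
  if (config$noise_sd > 0) {
    set.seed(config$seed + 211L +
               match(strain, names(config$strains)) * 1000L)
    noisy <- c("cdw", "co2", "glucose", "glutamate", "phosphate",
               "germA", "germB", "act", "red", "cda", "cpk")
    for (col in noisy) {
      out[[col]] <- pmax(out[[col]] *
                           (1 + rnorm(nrow(out), 0, config$noise_sd)), 0)
    }
    out$cdw <- pmax(out$cdw, 1e-6)
  }
  cultivation_ts(out)
}

# measured exchange rates at time t (mmol/gDW/h, negative = uptake)
toy_rates_at <- function(config, strain, time_h) {
  ps <- config$strains[[strain]]
  pre <- time_h < ps$t_depletion
  mu <- if (pre) ps$mu else 0
  q_glc <- if (pre) -ps$n_glc * ps$mu else -config$m_glc
  q_glu <- if (pre) -ps$n_glu * ps$mu else -config$m_glu
  list(mu = mu, rates = tibble(reaction = c("EX_glc", "EX_glu"),
                               rate = c(q_glc, q_glu)))
}

subsystem_of_protein <- function(model, proteins) {
  protein_of <- setNames(proteins$protein_id, proteins$gene_id)
  out <- list()
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    if (!nzchar(r$gene_rule)) next
    for (g in gene_rule_genes(r$gene_rule)) {
      out[[protein_of[[g]]]] <- r$subsystem
    }
  }
  out
}

# demand-proportional enzyme capacities: per strain and phase (pre/post
# switch), the needed flux through each catalyzed reaction is taken from
# two reference FBA states of the rate-constrained toy model — an anabolic
# vertex (maximal growth) and a respiratory vertex (maximal energy
# dissipation under the measured rates) — with planted capacities for the
# product pathways, which carry no flux at either reference optimum.
# Enzymes are then allocated so kcat * abundance = headroom * needed flux.
toy_capacity <- function(model, config, strain, phase) {
  ps <- config$strains[[strain]]
  pr <- config$proteome
  reference_need <- function(time_h) {
    rt <- toy_rates_at(config, strain, time_h)
    m <- model
    for (k in seq_len(nrow(rt$rates))) {
      m <- set_bounds(m, rt$rates$reaction[k],
                      lb = rt$rates$rate[k] * 1.08,
                      ub = rt$rates$rate[k] * 0.92)
    }
    m <- set_bounds(m, model$objective, lb = rt$mu * 0.92)
    # parsimonious reference state: minimum total flux satisfying the
    # measured rates and growth (the usual proteome-efficiency assumption)
    sp <- split_reversible(m)
    S <- stoich_matrix(sp)
    sol <- lp_solve(S, rep(0, nrow(S)), rep(-1, ncol(S)),
                    sp$reactions$lb, sp$reactions$ub, "max")
    if (sol$status != "optimal") {
      abort("synthetic reference state infeasible",
            class = "switchflux_infeasible")
    }
    v <- setNames(sol$x, sp$reactions$id)
    vapply(setNames(sp$split_map$original, sp$split_map$original),
           function(o) {
      mp <- sp$split_map[sp$split_map$original == o, ]
      max(if (is.na(mp$fwd)) 0 else v[[mp$fwd]],
          if (is.na(mp$bwd)) 0 else v[[mp$bwd]])
    }, numeric(1))
  }
  if (phase == "pre") {
    need <- reference_need(ps$t_depletion - 1)
  } else {
    need <- reference_need(ps$t_depletion + 1)
  }
  cap <- setNames(pmax(need, pr$floor_capacity), names(need))
  boost <- intersect(names(pr$capacity_boost), names(cap))
  cap[boost] <- cap[boost] * pr$capacity_boost[boost]
  bgc_rx <- c("ACTS", "REDS", "CDAS", "CPKS")
  cap[names(cap) %in% bgc_rx] <- pr$bgc_capacity[[phase]]
  cap[names(cap) %in% c("GERMAS", "GERMBS")] <- pr$germ_capacity[[phase]]
  if (phase == "post") {
    # post-switch primary metabolism retains a scaled-down pre-switch profile
    pre_cap <- toy_capacity(model, config, strain, "pre")
    scale <- setNames(rep(0.8, nrow(model$reactions)), model$reactions$id)
    for (ss in names(pr$post_factor)) {
      scale[model$reactions$id[model$reactions$subsystem == ss]] <-
        pr$post_factor[[ss]]
    }
    keep <- !names(cap) %in% c(bgc_rx, "GERMAS", "GERMBS")
    cap[keep] <- pmax(pre_cap[keep] * scale[names(cap)[keep]], cap[keep])
  }
  cap
}

#' Synthetic proteome samples
#'
#' Per sampling time (eight points straddling the strain's depletion time),
#' protein abundances are allocated proportional to the flux demand of the
#' reactions they catalyze (`abundance = headroom * flux / kcat`), with a
#' planted pre/post-switch shift: oxidative-phosphorylation enzymes up,
#' fatty-acid enzymes down after depletion. Log-normal multiplicative noise
#' is applied and a configured fraction of proteins is withheld as
#' unmeasured. Seeded and reproducible.
#'
#' @param model the strain's toy model.
#' @param timeseries the strain's [make_timeseries()] output.
#' @param config a [toy_config()].
#' @param kcats,proteins tables from [make_thermo_kcats()].
#' @return tibble `strain`, `time_h`, `protein_id`, `abundance`
#'   (mmol/gDW).
#' @export
make_proteome <- function(model, timeseries, config, kcats, proteins) {
  strain <- timeseries$strain[1]
  ps <- config$strains[[strain]]
  pr <- config$proteome
  set.seed(config$seed + 307L + match(strain, names(config$strains)) * 1000L)
  times <- ps$t_depletion + pr$offsets
  kc <- setNames(kcats$kcat[kcats$direction == "forward"],
                 paste(kcats$protein_id[kcats$direction == "forward"],
                       kcats$reaction_id[kcats$direction == "forward"]))
  cap_pre <- toy_capacity(model, config, strain, "pre")
  cap_post <- toy_capacity(model, config, strain, "post")
  protein_of <- setNames(proteins$protein_id, proteins$gene_id)

  abundance_phase <- function(cap) {
    e <- setNames(rep(0, nrow(proteins)), proteins$protein_id)
    for (i in seq_len(nrow(model$reactions))) {
      r <- model$reactions[i, ]
      if (!nzchar(r$gene_rule)) next
      alts <- gene_rule_dnf(r$gene_rule)
      for (alt in alts) {
        for (g in alt) {
          p <- protein_of[[g]]
          k <- kc[[paste(p, r$id)]]
          if (is.null(k)) k <- config$kcat_median
          want <- pr$headroom * cap[[r$id]] / (k * length(alts))
          e[p] <- max(e[p], want)
        }
      }
    }
    e
  }
  e_pre <- abundance_phase(cap_pre)
  e_post <- abundance_phase(cap_post)

  rows <- lapply(times, function(t0) {
    w <- 1 / (1 + exp(-(t0 - ps$t_depletion) / pr$transition_h))
    e <- e_pre * (1 - w) + e_post * w
    e <- e * exp(rnorm(length(e), 0, pr$noise_sdlog))
    keep <- runif(length(e)) >= pr$withheld_fraction
    tibble(strain = strain, time_h = t0,
           protein_id = names(e)[keep], abundance = unname(e[keep]))
  })
  out <- bind_rows(rows)
  # keep each sample's measured mass within the modeled protein budget
  mw <- setNames(proteins$mw, proteins$protein_id)
  budget <- config$pool$p_total * config$pool$f
  out <- ungroup(mutate(group_by(out, .data$time_h),
                        abundance = .data$abundance *
                          min(1, 0.9 * budget /
                                sum(.data$abundance * mw[.data$protein_id]))))
  out
}

#' Synthetic growth/knockout phenotype tests with planted confusion
#'
#' Builds a base set of growth-medium tests (carbon-source swaps and
#' nutrient omissions) and single-gene knockouts, labels them with the
#' model's own FBA ground truth, resamples them to the configured class
#' sizes, and flips the observed label of an exact planted number of tests
#' in each class, producing a deterministic confusion structure when the
#' tests are evaluated against the generating model.
#'
#' @param model the toy model.
#' @param config a [toy_config()].
#' @param growth_cutoff growth-call threshold used for the ground truth.
#' @return phenotype test tibble for [evaluate_phenotypes()].
#' @export
make_phenotype_tests <- function(model, config = toy_config(),
                                 growth_cutoff = 1e-6) {
  set.seed(config$seed + 401L)
  ref_medium <- c(EX_glc = config$uptake_glc, EX_glu = config$uptake_glu,
                  EX_pi = config$uptake_pi, EX_nh4 = 10, EX_o2 = 1000)
  medium <- function(drop = character(), add = NULL) {
    m <- ref_medium[setdiff(names(ref_medium), drop)]
    c(m, add)
  }
  media <- list(reference = medium(),
                glucose_only = medium(drop = "EX_glu"),
                glutamate_only = medium(drop = "EX_glc"),
                no_phosphate = medium(drop = "EX_pi"),
                no_ammonium = medium(drop = "EX_nh4"),
                anaerobic = medium(drop = "EX_o2"))
  base <- bind_rows(
    tibble(test_id = paste0("medium_", names(media)),
           kind = "growth_medium", spec = unname(media)),
    tibble(test_id = paste0("ko_", model$genes), kind = "knockout",
           spec = lapply(model$genes, identity)))
  truth <- evaluate_phenotypes(model, mutate(base, observed = TRUE),
                               growth_cutoff)
  base$truth <- attr(truth, "predictions")$predicted

  ph <- config$phenotype
  draw <- function(pool, n) pool[sample.int(nrow(pool), n, replace = TRUE), ]
  pos <- draw(filter(base, .data$truth), ph$n_growth)
  neg <- draw(filter(base, !.data$truth), ph$n_nogrowth)
  tests <- bind_rows(pos, neg)
  tests$observed <- tests$truth
  flip_pos <- sample(which(tests$truth), ph$flip_growth)
  flip_neg <- sample(which(!tests$truth), ph$flip_nogrowth)
  tests$observed[c(flip_pos, flip_neg)] <- !tests$observed[c(flip_pos, flip_neg)]
  tests$test_id <- paste0(tests$test_id, "_", seq_len(nrow(tests)))
  select(tests, "test_id", "kind", "spec", "observed")
}

#' Condition specifications for a strain's sampling times
#'
#' One [condition_spec()] per proteome sampling time, carrying the
#' generator's measured exchange rates, growth rate and proteome sample,
#' plus the specific CO2 evolution rate used as pathway-activity divisor.
#'
#' @param config a [toy_config()].
#' @param strain strain preset name.
#' @param proteome [make_proteome()] output for the strain.
#' @param timeseries [make_timeseries()] output for the strain.
#' @return named list of `condition_spec`s (names `"<strain>@<time>"`) with
#'   attribute `co2_rate` (specific rates, mmol/gDW/h).
#' @export
make_conditions <- function(config, strain, proteome, timeseries) {
  times <- sort(unique(proteome$time_h))
  conds <- list()
  co2 <- numeric()
  for (t0 in times) {
    rt <- toy_rates_at(config, strain, t0)
    prot <- proteome[proteome$time_h == t0, c("protein_id", "abundance")]
    nm <- paste0(strain, "@", t0)
    conds[[nm]] <- condition_spec(strain, t0, rt$rates, rt$mu, prot)
    co2[nm] <- interp_at(timeseries$time_h, timeseries$co2, t0) /
      interp_at(timeseries$time_h, timeseries$cdw, t0)
  }
  attr(conds, "co2_rate") <- co2
  conds
}

#' Expression matrix from proteome samples
#'
#' @param proteome one or more [make_proteome()] outputs, row-bound.
#' @return an `expression_matrix` (missing protein/time combinations filled
#'   with 0).
#' @export
proteome_expression <- function(proteome) {
  long <- mutate(as_tibble(proteome), feature_id = .data$protein_id,
                 replicate = 1L, value = .data$abundance)
  m <- as_expression_matrix(long[, c("feature_id", "strain", "time_h",
                                     "replicate", "value")])
  m$values[is.na(m$values)] <- 0
  m
}

#' Default phosphate-responsive regulon of the toy proteome
#'
#' @param model the toy model.
#' @param proteins protein table from [make_thermo_kcats()].
#' @param subsystems subsystems whose enzymes shift at the switch.
#' @return character vector of protein ids.
#' @export
toy_regulon <- function(model, proteins,
                        subsystems = "Oxidative phosphorylation") {
  ss <- subsystem_of_protein(model, proteins)
  names(ss)[unlist(ss) %in% subsystems]
}
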