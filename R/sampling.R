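# Unbiased flux estimation by random vertex sampling: each draw maximizes
# an objective with i.i.d. standard-normal coefficients over all reactions,
# and the optimal basic solution (a vertex of the flux polytope) is stored.
# Means over vertices summarize pathway activity without committing to a
# single cellular objective.

#' Sample vertices of the flux polytope
#'
#' @param model a `metabolic_model` (or `ec_model`).
#' @param n number of vertices to draw.
#' @param seed integer seed; identical seeds give identical sample matrices.
#' @return a `flux_sample_set`: list with `samples` (n x reactions matrix),
#'   `objectives` (the random objective matrix), `seed` and `model`.
#' @export
sample_vertices <- function(model, n, seed = 1L) {
  stopifnot(n >= 1)
  st <- fba_status(model)
  if (st$status != "optimal") {
    abort(paste0("model is ", st$status, "; cannot sample"),
          class = "switchflux_infeasible")
  }
  S <- stoich_matrix(model)
  b <- rep(0, nrow(S))
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  nr <- ncol(S)
  set.seed(seed)
  W <- matrix(rnorm(n * nr), nrow = n)
  X <- matrix(NA_real_, n, nr, dimnames = list(NULL, model$reactions$id))
  for (k in seq_len(n)) {
    c_vec <- W[k, ]
    for (attempt in 1:6) {
      sol <- lp_solve(S, b, c_vec, lb, ub, "max")
      if (sol$status == "optimal") break
      if (sol$status == "unbounded") {
        # clamp the dominant unbounded direction and retry
        j <- which.max(abs(c_vec))
        inform(paste0("unbounded random objective; clamping direction of '",
                      model$reactions$id[j], "'"))
        c_vec[j] <- 0
      } else {
        abort(paste0("sampling LP returned ", sol$status),
              class = "switchflux_lp_error")
      }
    }
    if (sol$status != "optimal") {
      abort("could not resolve unbounded sampling LP",
            class = "switchflux_lp_error")
    }
    X[k, ] <- sol$x
  }
  structure(list(samples = X, objectives = W, seed = seed, model = model),
            class = "flux_sample_set")
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat("<flux_sample_set> ", nrow(x$samples), " vertices x ",
      ncol(x$samples), " reactions (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Mean fluxes of a vertex sample
#'
#' For ec-models the means are collapsed to net fluxes on the original
#' reactions.
#'
#' @param fss a `flux_sample_set`.
#' @param collapse collapse ec copies to original net fluxes (default when
#'   the sampled model is an `ec_model`).
#' @return tibble `reaction`, `flux`.
#' @export
sample_means <- function(fss, collapse = inherits(fss$model, "ec_model")) {
  m <- colMeans(fss$samples)
  if (collapse) {
    ec_net_fluxes(fss$model, setNames(m, colnames(fss$samples)))
  } else {
    tibble(reaction = colnames(fss$samples), flux = unname(m))
  }
}

#' CO2-normalized pathway activity Z-scores
#'
#' Per condition, pathway activity is the sum of |mean flux| over member
#' reactions, divided by that condition's CO2 evolution rate; activities
#' are then Z-scored per pathway across the standardization set (all
#' conditions jointly, or per strain). Pathways are ranked by the variance
#' of their normalized activity and the `top_k` most variable retained
#' (plus any `force_include` pathways). Zero-variance rows are emitted as 0
#' and flagged rather than NaN.
#'
#' @param samples_per_condition named list of `flux_sample_set`s; names are
#'   condition labels, conventionally `"<strain>@<time>"`.
#' @param subsystems named character vector reaction -> pathway; defaults to
#'   the first model's subsystem column. Reactions with an empty label are
#'   ignored.
#' @param co2_rate named positive numeric, one entry per condition (the
#'   measured CO2 evolution rate used as normalization divisor).
#' @param top_k number of most-varying pathways retained.
#' @param force_include pathway names always retained.
#' @param standardize `"joint"` (all conditions) or `"per_strain"` (strain
#'   parsed from the condition label before `"@"`).
#' @param signed use the signed sum of mean fluxes instead of |mean flux|.
#' @return a `pathway_activity` tibble: `pathway`, `condition`, `strain`,
#'   `time_h`, `raw`, `normalized`, `zscore`, `flag`.
#' @export
pathway_activity <- function(samples_per_condition, subsystems = NULL,
                             co2_rate, top_k = 10, force_include = NULL,
                             standardize = c("joint", "per_strain"),
                             signed = FALSE) {
  standardize <- match.arg(standardize)
  conds <- names(samples_per_condition)
  stopifnot(length(conds) > 0, all(conds %in% names(co2_rate)))
  if (any(co2_rate[conds] <= 0)) {
    abort("co2_rate must be positive for every condition",
          class = "switchflux_usage_error")
  }
  if (is.null(subsystems)) {
    m0 <- samples_per_condition[[1]]$model
    base <- if (inherits(m0, "ec_model")) {
      # label original reactions via their total-flux representative (the
      # arm reaction when isozymes were split)
      orig <- m0$net_map$original
      idx <- match(ifelse(is.na(m0$net_map$fwd), m0$net_map$bwd,
                          m0$net_map$fwd), m0$reactions$id)
      setNames(m0$reactions$subsystem[idx], orig)
    } else {
      setNames(m0$reactions$subsystem, m0$reactions$id)
    }
    subsystems <- base[!is.na(base) & nzchar(base)]
  }
  act <- lapply(conds, function(cn) {
    mf <- sample_means(samples_per_condition[[cn]])
    mf <- mf[mf$reaction %in% names(subsystems), ]
    mf$pathway <- unname(subsystems[mf$reaction])
    agg <- if (signed) {
      summarise(group_by(mf, .data$pathway), raw = sum(.data$flux),
                .groups = "drop")
    } else {
      summarise(group_by(mf, .data$pathway), raw = sum(abs(.data$flux)),
                .groups = "drop")
    }
    mutate(agg, condition = cn, normalized = .data$raw / co2_rate[[cn]])
  })
  long <- bind_rows(act)
  long <- mutate(long,
                 strain = sub("@.*$", "", .data$condition),
                 time_h = suppressWarnings(as.numeric(sub("^.*@", "",
                                                          .data$condition))))
  ranking <- summarise(group_by(long, .data$pathway),
                       v = var(.data$normalized), .groups = "drop")
  ranking$v[is.na(ranking$v)] <- 0
  keep <- head(arrange(ranking, desc(.data$v))$pathway, top_k)
  keep <- union(keep, intersect(force_include, long$pathway))
  long <- filter(long, .data$pathway %in% keep)
  grp <- if (standardize == "joint") rep("all", nrow(long)) else long$strain
  long$group <- grp
  long <- ungroup(mutate(
    group_by(long, .data$pathway, .data$group),
    mu_ = mean(.data$normalized), sd_ = sd(.data$normalized),
    flag = ifelse(is.na(.data$sd_) | .data$sd_ == 0, "zero_variance", "ok"),
    zscore = ifelse(.data$flag == "zero_variance", 0,
                    (.data$normalized - .data$mu_) / .data$sd_)))
  out <- select(long, "pathway", "condition", "strain", "time_h",
                "raw", "normalized", "zscore", "flag")
  structure(out, class = c("pathway_activity", class(out)),
            standardize = standardize, co2_rate = co2_rate[conds])
}

#' Source/sink budget of a metabolite
#'
#' Partitions each reaction's signed stoichiometric production rate
#' (coefficient x flux) into producing and consuming contributions; at
#' steady state the two sides balance.
#'
#' @param fluxes a flux tibble (`reaction`, `flux`), typically
#'   [sample_means()] output.
#' @param model the model the fluxes live on (original reaction space).
#' @param metabolite metabolite id.
#' @return a `metabolite_budget` tibble: `reaction`, `role`
#'   (`"producing"`/`"consuming"`), `rate` (non-negative); attributes
#'   `production_total`, `consumption_total`, `metabolite`.
#' @export
metabolite_budget <- function(fluxes, model, metabolite) {
  if (!metabolite %in% model$metabolites$id) {
    abort(paste0("metabolite '", metabolite, "' not in model"),
          class = "switchflux_model_error")
  }
  v <- setNames(fluxes$flux, fluxes$reaction)
  rows <- list()
  for (i in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoichiometry[[i]]
    if (!metabolite %in% names(s)) next
    rid <- model$reactions$id[i]
    if (!rid %in% names(v)) next
    rate <- s[[metabolite]] * v[[rid]]
    if (abs(rate) < 1e-12) next
    rows[[length(rows) + 1]] <- tibble(
      reaction = rid,
      role = if (rate > 0) "producing" else "consuming",
      rate = abs(rate))
  }
  out <- bind_rows(rows)
  if (!nrow(out)) out <- tibble(reaction = character(), role = character(),
                                rate = numeric())
  structure(out, class = c("metabolite_budget", class(out)),
            metabolite = metabolite,
            production_total = sum(out$rate[out$role == "producing"]),
            consumption_total = sum(out$rate[out$role == "consuming"]))
}
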