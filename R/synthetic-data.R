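#' Specify one simulated gene
#'
#' A gene is described by its `role` and by its per-condition multiplicative
#' expression factor delta relative to the control condition (control is
#' implicitly 1). Stable reference genes must have delta = 1 everywhere;
#' pathway members must name their pathway.
#'
#' @param gene_id gene symbol.
#' @param role one of `"reference_stable"`, `"reference_unstable"`,
#'   `"pathway_member"`, `"filler"`.
#' @param pathway pathway name (required for `pathway_member`).
#' @param effects named numeric vector of delta values per non-control
#'   condition; conditions not named default to 1.
#' @return a `gene_spec` list.
#' @export
gene_spec <- function(gene_id,
                      role = c("reference_stable", "reference_unstable",
                               "pathway_member", "filler"),
                      pathway = NULL, effects = NULL) {
  role <- match.arg(role)
  if (!is.character(gene_id) || length(gene_id) != 1L || !nzchar(gene_id))
    stopf("gene_id must be a single non-empty string")
  effects <- effects %||% numeric(0)
  if (length(effects) && (is.null(names(effects)) || any(names(effects) == "")))
    stopf("effects must be named by condition (gene '%s')", gene_id)
  if (any(!is.finite(effects)) || any(effects <= 0))
    stopf("all effects must be finite and > 0 (gene '%s')", gene_id)
  if (role == "reference_stable" && length(effects) && any(effects != 1))
    stopf("reference_stable gene '%s' must have all effects = 1", gene_id)
  if (role == "pathway_member" && is.null(pathway))
    stopf("pathway_member gene '%s' must name a pathway", gene_id)
  structure(list(gene_id = gene_id, role = role,
                 pathway = pathway, effects = effects),
            class = "gene_spec")
}

#' Assemble a simulation configuration
#'
#' Defines the study layout the generator emulates: an ordered set of
#' conditions (first = control), a number of replicate arrays per
#' condition, per-gene multiplicative effects, log-normal measurement
#' noise on the log2 scale, and log-uniform per-gene baseline intensities.
#'
#' @param conditions ordered character vector of condition labels; the
#'   first is the control.
#' @param genes list of [gene_spec()] objects.
#' @param replicates_per_condition arrays per condition (>= 2; default 4).
#' @param noise_sd_log2 SD of the log2-scale multiplicative noise (>= 0).
#' @param baseline_range_log10 range (log10 intensity units) of the
#'   per-gene baseline draw.
#' @param probe_multiplicity probes per gene on the simulated array.
#' @param pathways optional named list of pathway member vectors; derived
#'   from the gene specs when omitted.
#' @param seed integer RNG seed stored with the configuration.
#' @return a `sim_config` object.
#' @export
simulation_config <- function(conditions, genes,
                              replicates_per_condition = 4L,
                              noise_sd_log2 = 0.15,
                              baseline_range_log10 = c(2, 5),
                              probe_multiplicity = 1L,
                              pathways = NULL,
                              seed = 1L) {
  if (length(conditions) < 2L) stopf("need a control plus at least one condition")
  if (anyDuplicated(conditions)) stopf("condition labels must be unique")
  if (replicates_per_condition < 2L) stopf("replicates_per_condition must be >= 2")
  if (!is.finite(noise_sd_log2) || noise_sd_log2 < 0)
    stopf("noise_sd_log2 must be a non-negative real")
  if (length(baseline_range_log10) != 2L ||
      diff(baseline_range_log10) <= 0)
    stopf("baseline_range_log10 must be an increasing pair")
  if (probe_multiplicity < 1L) stopf("probe_multiplicity must be >= 1")
  if (!length(genes)) stopf("at least one gene is required")
  if (!all(vapply(genes, inherits, logical(1L), "gene_spec")))
    stopf("genes must be a list of gene_spec objects")
  ids <- vapply(genes, `[[`, character(1L), "gene_id")
  if (anyDuplicated(ids)) stopf("duplicated gene id '%s'", ids[duplicated(ids)][1L])

  control <- conditions[1L]
  delta <- matrix(1, length(ids), length(conditions),
                  dimnames = list(ids, conditions))
  for (g in genes) {
    bad <- setdiff(names(g$effects), conditions[-1L])
    if (length(bad))
      stopf("gene '%s' has an effect for unknown condition '%s'", g$gene_id, bad[1L])
    delta[g$gene_id, names(g$effects)] <- g$effects
  }
  roles <- setNames(vapply(genes, `[[`, character(1L), "role"), ids)
  pw <- setNames(vapply(genes, function(g) g$pathway %||% NA_character_,
                        character(1L)), ids)
  if (is.null(pathways)) {
    members <- !is.na(pw)
    pathways <- split(ids[members], pw[members])
  }
  structure(list(conditions = conditions, control = control,
                 gene_ids = ids, roles = roles, pathway_of = pw,
                 pathways = pathways, delta = delta,
                 replicates_per_condition = as.integer(replicates_per_condition),
                 noise_sd_log2 = noise_sd_log2,
                 baseline_range_log10 = baseline_range_log10,
                 probe_multiplicity = as.integer(probe_multiplicity),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d genes x %d conditions (%s control), ",
                     "%d replicates, noise_sd_log2 = %g, %d probe(s)/gene\n"),
              length(x$gene_ids), length(x$conditions), x$control,
              x$replicates_per_condition, x$noise_sd_log2,
              x$probe_multiplicity), ...)
  invisible(x)
}

#' Gene panels of the simulated glucose-metabolism pathways
#'
#' Membership of the glycolysis, TCA-cycle and electron-transport-chain
#' panels measured in the emulated study.
#'
#' @return named list of character vectors.
#' @export
scenario_panels <- function() {
  list(glycolysis = c("Hk", "Gpi", "Aldoc", "Gapdh", "Tpi", "Pgk1",
                      "Pgam1", "Eno1", "Eno2", "Pk", "Pkm2"),
       tca = c("Pdha1", "Aco2", "Idh", "Ogdh", "Sdh", "Mdh2"),
       etc = c("Atp5a1", "Atp5b", "Cox", "MT-ND2", "Cyc1"))
}

#' Per-condition calibration of the default scenario
#'
#' For every non-control condition: the downregulated members of each
#' pathway, the pathway-level flux index their effects must multiply to
#' (the published per-pathway CFI values the scenario is calibrated
#' against), and any upregulated member with its fold change.
#'
#' @return named list (one element per condition) with fields `down`
#'   (list of member vectors per pathway), `cfi` (named numeric) and `up`
#'   (named numeric).
#' @export
scenario_calibration <- function() {
  list(
    "G+/M-" = list(
      down = list(glycolysis = c("Hk", "Gpi", "Gapdh", "Pgk1", "Eno1", "Pk"),
                  tca = c("Pdha1", "Ogdh", "Idh", "Aco2"),
                  etc = c("Atp5a1", "Atp5b", "Cyc1", "Cox", "MT-ND2")),
      cfi = c(glycolysis = 0.0192, tca = 0.0602, etc = 0.0119),
      up = c()),
    "G+/M+" = list(
      down = list(glycolysis = c("Hk", "Gpi", "Gapdh", "Tpi", "Pgk1", "Eno1", "Pk"),
                  tca = c("Pdha1", "Mdh2", "Sdh", "Ogdh", "Idh", "Aco2"),
                  etc = c("Atp5a1", "Atp5b", "Cyc1", "Cox", "MT-ND2")),
      cfi = c(glycolysis = 0.0047, tca = 0.0024, etc = 0.017),
      up = c(Pgam1 = 2.5)),
    "Med" = list(
      down = list(glycolysis = c("Hk", "Gpi", "Gapdh", "Tpi", "Pgk1", "Eno1", "Pk"),
                  tca = c("Pdha1", "Sdh", "Ogdh", "Idh", "Aco2"),
                  etc = c("Atp5a1", "Atp5b", "Cyc1", "Cox", "MT-ND2")),
      cfi = c(glycolysis = 0.0019, tca = 0.0124, etc = 0.0328),
      up = c()),
    "PPMS" = list(
      down = list(glycolysis = c("Hk", "Gpi", "Gapdh", "Eno2", "Pk"),
                  tca = c("Aco2"),
                  etc = c("Atp5a1", "Cox", "MT-ND2")),
      cfi = c(glycolysis = 0.0033, tca = 0.5400, etc = 0.0728),
      up = c()),
    "NMO" = list(
      down = list(glycolysis = c("Gpi", "Aldoc", "Gapdh", "Tpi", "Pgk1", "Eno1", "Pk"),
                  tca = c("Pdha1", "Mdh2", "Sdh", "Ogdh", "Aco2"),
                  etc = c("Atp5a1", "Atp5b", "Cyc1", "Cox", "MT-ND2")),
      cfi = c(glycolysis = 0.0013, tca = 0.0055, etc = 0.0149),
      up = c())
  )
}

#' Default simulated study scenario
#'
#' Six conditions (Control, G+/M-, G+/M+, Med, PPMS, NMO) with four
#' replicate arrays each, mirroring the CSF-treated OPC study layout:
#'
#' * four stable reference genes (Mrpl19, Hprt, B2m, Tfrc; delta = 1
#'   everywhere),
#' * ActB as a deliberately unstable housekeeping gene (condition-dependent
#'   delta in 0.37-0.63),
#' * the glycolysis / TCA-cycle / electron-transport-chain panels, with the
#'   downregulated members of each condition sharing an equal delta chosen
#'   so the product over the set equals that condition's published pathway
#'   flux index exactly (Gapdh sits in the glycolysis panel, which makes it
#'   the second unstable housekeeping candidate), and Pgam1 upregulated
#'   2.5-fold in G+/M+,
#' * `n_filler` inert genes spanning the full baseline intensity range so
#'   the low-expression filter has something to remove.
#'
#' Measured (reference/pathway) genes draw their baselines from the bright
#' top 40% of `baseline_range_log10` — they were detectably expressed in
#' the emulated study, so the generator guarantees they clear the pooled
#' low-expression filter threshold — while filler spans the whole range.
#'
#' @param noise_sd_log2 log2-scale noise SD (default 0.15, a typical
#'   one-color array replicate CV of ~11%).
#' @param replicates_per_condition arrays per condition (default 4).
#' @param n_filler number of inert background genes (default 200).
#' @param probe_multiplicity probes per gene (default 2, so probe merging
#'   is exercised).
#' @param seed stored RNG seed.
#' @return a `sim_config`.
#' @examples
#' cfg <- default_scenario()
#' # configured glycolysis product for G+/M+ equals the calibrated 0.0047
#' prod(cfg$delta[scenario_calibration()[["G+/M+"]]$down$glycolysis, "G+/M+"])
#' @export
default_scenario <- function(noise_sd_log2 = 0.15,
                             replicates_per_condition = 4L,
                             n_filler = 200L,
                             probe_multiplicity = 2L,
                             seed = 1L) {
  conds <- c("Control", "G+/M-", "G+/M+", "Med", "PPMS", "NMO")
  panels <- scenario_panels()
  calib <- scenario_calibration()

  # effects per pathway gene: equal delta within each condition's down set,
  # so the set product equals the calibrated pathway index exactly
  eff <- lapply(setNames(nm = unlist(panels, use.names = FALSE)),
                function(g) numeric(0))
  for (cond in names(calib)) {
    cc <- calib[[cond]]
    for (pw in names(cc$down)) {
      members <- cc$down[[pw]]
      d <- exp(log(cc$cfi[[pw]]) / length(members))
      for (g in members) eff[[g]][cond] <- d
    }
    for (g in names(cc$up)) eff[[g]][cond] <- cc$up[[g]]
  }

  genes <- list(
    gene_spec("Mrpl19", "reference_stable"),
    gene_spec("Hprt",   "reference_stable"),
    gene_spec("B2m",    "reference_stable"),
    gene_spec("Tfrc",   "reference_stable"),
    # ActB: expression fractions mirroring the reported 37% (G+/M+),
    # 42% (Med) and 63% (NMO) levels, mid-range drift elsewhere
    gene_spec("ActB", "reference_unstable",
              effects = c("G+/M-" = 0.55, "G+/M+" = 0.37, "Med" = 0.42,
                          "PPMS" = 0.60, "NMO" = 0.63))
  )
  for (pw in names(panels))
    for (g in panels[[pw]])
      genes <- c(genes, list(gene_spec(g, "pathway_member", pathway = pw,
                                       effects = eff[[g]])))
  if (n_filler > 0L)
    genes <- c(genes, lapply(sprintf("filler%03d", seq_len(n_filler)),
                             gene_spec, role = "filler"))

  simulation_config(conditions = conds, genes = genes,
                    replicates_per_condition = replicates_per_condition,
                    noise_sd_log2 = noise_sd_log2,
                    baseline_range_log10 = c(2, 5),
                    probe_multiplicity = probe_multiplicity,
                    pathways = panels, seed = seed)
}

#' Global-null variant of a scenario
#'
#' Returns the same configuration with every effect reset to 1 (no gene
#' responds to any condition). Used for type-I-error calibration of the
#' differential-expression caller and the flux index.
#'
#' @param config a `sim_config`.
#' @return a `sim_config` with all delta = 1.
#' @export
null_scenario <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$delta[] <- 1
  config
}

#' Candidate reference genes of a scenario
#'
#' The stability-candidate panel: stable and unstable reference genes plus
#' Gapdh, the classical housekeeping gene that doubles as a glycolysis
#' member (its condition-dependent downregulation is what makes it an
#' unstable candidate).
#'
#' @param config a `sim_config`.
#' @return character vector of candidate gene ids.
#' @export
scenario_candidates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cand <- names(config$roles)[config$roles %in%
                                c("reference_stable", "reference_unstable")]
  union(cand, intersect("Gapdh", config$gene_ids))
}

#' Probe-to-gene map implied by a scenario
#'
#' @param config a `sim_config`.
#' @return data.frame with columns `probe_id`, `gene_id` (one row per
#'   simulated probe).
#' @export
scenario_probe_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$probe_multiplicity
  data.frame(
    probe_id = probe_ids(config$gene_ids, k),
    gene_id = rep(config$gene_ids, each = k),
    stringsAsFactors = FALSE)
}

probe_ids <- function(gene_ids, k) {
  if (k == 1L) gene_ids
  else paste0(rep(gene_ids, each = k), "_p", seq_len(k))
}

#' Configured flux-index truth of a scenario
#'
#' For each condition and pathway, the product of the configured delta over
#' all perturbed members (`configured`), and the same product restricted to
#' members whose delta clears the fold-change call cutoff
#' (`callable`, delta <= 1/fc_cutoff or >= fc_cutoff). The callable product
#' is what an ideal noise-free run of the pipeline reports: members whose
#' configured effect sits inside the fold-change window are never called,
#' so they contribute a factor of 1.
#'
#' @param config a `sim_config` carrying pathway definitions.
#' @param fc_cutoff fold-change call cutoff (default 2).
#' @return data.frame with columns `condition`, `pathway`, `configured`,
#'   `callable`; a `"totals"` attribute holds per-condition products.
#' @export
scenario_expected_cfi <- function(config, fc_cutoff = 2) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(config$pathways)) stopf("config carries no pathway definitions")
  grid <- expand.grid(condition = setdiff(config$conditions, config$control),
                      pathway = names(config$pathways),
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    members <- config$pathways[[grid$pathway[i]]]
    d <- config$delta[members, grid$condition[i]]
    callable <- d <= 1 / fc_cutoff | d >= fc_cutoff
    data.frame(condition = grid$condition[i], pathway = grid$pathway[i],
               configured = prod(d[d != 1]),
               callable = prod(d[callable]),
               stringsAsFactors = FALSE)
  }))
  totals <- do.call(rbind, lapply(split(res, res$condition), function(s)
    data.frame(condition = s$condition[1L],
               configured = prod(s$configured), callable = prod(s$callable),
               stringsAsFactors = FALSE)))
  rownames(totals) <- NULL
  attr(res, "totals") <- totals
  res
}

#' Generate a seeded synthetic expression matrix
#'
#' Each probe of gene g in a sample of condition c takes the value
#' `baseline(g) * probe_affinity * delta(g, c) * 2^eps`, with
#' `eps ~ Normal(0, noise_sd_log2)` drawn independently per probe and
#' sample. Probe affinities of a gene multiply to 1, so the geometric mean
#' over a gene's probes recovers `baseline(g) * delta(g, c) * noise`.
#' Output is deterministic given the configuration and seed; the caller's
#' RNG state is left untouched.
#'
#' @param config a `sim_config`.
#' @param seed_override optional integer replacing `config$seed`.
#' @return an `expr_matrix` (one row per probe) with attributes
#'   `gene_truth` (noise-free gene-level matrix `baseline * delta`) and
#'   `baseline` (per-gene baselines).
#' @export
generate_expression <- function(config, seed_override = NULL) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  if (config$noise_sd_log2 < 0) stopf("noise_sd_log2 must be >= 0")
  seed <- seed_override %||% config$seed
  ng <- length(config$gene_ids)
  k <- config$probe_multiplicity
  reps <- config$replicates_per_condition
  samples <- paste0(rep(config$conditions, each = reps), "_r",
                    rep(seq_len(reps), times = length(config$conditions)))
  cond_of <- setNames(rep(config$conditions, each = reps), samples)

  with_seed(seed, {
    lo <- config$baseline_range_log10[1L]
    hi <- config$baseline_range_log10[2L]
    # measured genes draw from the bright top 40% of the range so that even
    # a strongly downregulated gene's median stays safely above the pooled
    # 30% filter threshold set by the full-range filler background
    measured <- config$roles != "filler"
    base_lo <- ifelse(measured, lo + 0.6 * (hi - lo), lo)
    baseline <- setNames(10^runif(ng, base_lo, hi), config$gene_ids)
    # per-probe affinities, centred per gene so they multiply to 1
    aff <- matrix(0, ng, k)
    if (k > 1L) {
      aff <- matrix(rnorm(ng * k, 0, 0.3), ng, k)
      aff <- aff - rowMeans(aff)
    }
    eps <- matrix(rnorm(ng * k * length(samples), 0, config$noise_sd_log2),
                  ng * k, length(samples))
    gene_level <- baseline * config$delta[, cond_of[samples], drop = FALSE]
    # as.vector(t(aff)) orders affinities gene1 p1..pk, gene2 p1..pk, ...
    v <- gene_level[rep(seq_len(ng), each = k), , drop = FALSE] *
      2^as.vector(t(aff)) * 2^eps
    rownames(v) <- probe_ids(config$gene_ids, k)
    colnames(v) <- samples
    x <- expression_matrix(v, cond_of)
    truth <- baseline * config$delta
    colnames(truth) <- config$conditions
    attr(x, "gene_truth") <- truth
    attr(x, "baseline") <- baseline
    x
  })
}
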