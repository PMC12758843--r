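#' Scenario configuration for synthetic study data
#'
#' Bundles the ground truth and instrument settings used by all synthetic
#' generators. The two strain presets carry the study's photonic parameters:
#' the wild type has an in-plane period of 410 nm and the moeA deletion
#' mutant 365 nm, both with effective index 1.38 and multilayer spacing
#' `period * sqrt(3) / 2` (hexagonal row stacking). Scattering is acquired
#' at 60 degrees incidence on a 1-degree detector over 250-800 nm; specular
#' scans incidence 15-65 degrees in 5-degree steps over 400-1200 nm, wide
#' enough to contain the whole Bragg-Snell dispersion curve.
#'
#' @param strain `"WT"` or `"dmoeA"`.
#' @param seed Integer master seed recorded in all generated outputs.
#' @param noise_sd Multiplicative log-normal noise sd on scattering map
#'   values (default 0.05).
#' @param specular_center_jitter Multiplicative jitter on specular peak
#'   centers (default 0.01, i.e. 1 percent).
#' @param n_proteins,effect_fraction,effect_size_log2,complete_fraction,replicates,replicate_sigma
#'   Proteome truth: table size, fraction of proteins with a planted
#'   differential effect, planted |log2fc|, fraction with a planted
#'   complete-pattern absence, replicates per group, and log-normal
#'   replicate noise sd (natural-log scale).
#' @return A list of class `scenario_config` with elements `model`
#'   ([photonic_model()]), `scattering`/`specular` ([instrument_config()])
#'   and the remaining settings.
#' @export
#' @examples
#' scenario_config("WT")$model
scenario_config <- function(strain = c("WT", "dmoeA"), seed = 1,
                            noise_sd = 0.05,
                            specular_center_jitter = 0.01,
                            n_proteins = 1000, effect_fraction = 0.10,
                            effect_size_log2 = 2, complete_fraction = 0.02,
                            replicates = 3, replicate_sigma = 0.25) {
  strain <- match.arg(strain)
  period <- switch(strain, WT = 410, dmoeA = 365)
  structure(
    list(
      strain = strain,
      seed = as.integer(seed),
      model = photonic_model(period_a = period, n_avg = 1.38),
      scattering = instrument_config("scattering", incidence_deg = 60),
      specular = instrument_config("specular"),
      noise_sd = noise_sd,
      specular_center_jitter = specular_center_jitter,
      n_proteins = n_proteins,
      effect_fraction = effect_fraction,
      effect_size_log2 = effect_size_log2,
      complete_fraction = complete_fraction,
      replicates = replicates,
      replicate_sigma = replicate_sigma
    ),
    class = "scenario_config"
  )
}

#' Generate a matched pair of goniometry maps
#'
#' One scattering and one specular reflectance map from the scenario's
#' photonic truth, with the truth, strain and seeds embedded in the map
#' metadata. Regeneration with the same config is bit-identical.
#'
#' @param config A [scenario_config()].
#' @return A list with elements `scattering` and `specular`, both
#'   [spectral_map()]s.
#' @export
make_goniometry_pair <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  scattering <- simulate_scattering_map(
    config$model, config$scattering,
    noise_sd = config$noise_sd, seed = config$seed
  )
  specular <- simulate_specular_map(
    config$model, config$specular,
    noise_sd = 0.02, center_jitter = config$specular_center_jitter,
    seed = config$seed + 1L
  )
  scattering$metadata$strain <- config$strain
  specular$metadata$strain <- config$strain
  list(scattering = scattering, specular = specular)
}

#' Deterministic MoCo presence/absence fixtures
#'
#' Builds the two presence/absence matrices of the comparative-genomics
#' summary with fixed, documented gene-loss assignments. The SC matrix has
#' 87 genomes: 61 with the complete eight-gene pathway, 10 missing moaD
#' only, and 16 missing both mobA and moaD (the two genes below 100 percent
#' prevalence in SC strains). The non-SC matrix has 30 genomes: 6 complete,
#' 6 missing the entire pathway, and 18 each missing moaD, moaE and moaC2.
#' These matrices reproduce the completeness bookkeeping exactly; their
#' per-gene marginals are a fixture choice, not a reconstruction of any
#' real genome set.
#'
#' @return A list with tibbles `sc` (87 x 8 genes) and `non_sc` (30 x 8),
#'   each with `genome` and `class` columns plus 0/1 gene columns.
#' @export
make_presence_fixtures <- function() {
  genes <- moco_genes()
  ones <- function(n) matrix(1L, nrow = n, ncol = length(genes),
                             dimnames = list(NULL, genes))

  sc <- ones(87)
  sc[62:71, "moaD"] <- 0L
  sc[72:87, c("mobA", "moaD")] <- 0L
  sc_tbl <- dplyr::bind_cols(
    tibble::tibble(genome = sprintf("SC_%03d", 1:87), class = "SC"),
    tibble::as_tibble(sc)
  )

  nsc <- ones(30)
  nsc[7:12, ] <- 0L
  nsc[13:30, c("moaD", "moaE", "moaC2")] <- 0L
  nsc_tbl <- dplyr::bind_cols(
    tibble::tibble(genome = sprintf("NSC_%03d", 1:30), class = "non-SC"),
    tibble::as_tibble(nsc)
  )
  list(sc = sc_tbl, non_sc = nsc_tbl)
}

#' Generate a synthetic two-strain abundance table with known truth
#'
#' Draws per-protein baseline abundances (log-normal), applies log-normal
#' replicate noise, plants differential effects of +/- `effect_size_log2`
#' log2 units in a fraction of proteins, and sets another fraction to
#' complete-pattern absence (all replicates of one group not detected).
#' Accessions follow the PAM9xxxx style. The returned truth labels allow
#' recovery scoring of any downstream calling procedure.
#'
#' @param config A [scenario_config()]; its proteome fields set the table
#'   size, effect fraction and sizes, replicate count and noise.
#' @return A list with `abundance` (long tibble: `accession`, `group`,
#'   `replicate`, `abundance`, `NA` = not detected) and `truth` (tibble:
#'   `accession`, `true_class` in up/down/null/induced_complete/
#'   repressed_complete, `true_log2fc`).
#' @export
make_abundance_table <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_proteins
  reps <- config$replicates
  with_seed_if(config$seed, {
    accession <- sprintf("PAM9%04d", seq_len(n))
    n_eff <- round(config$effect_fraction * n)
    n_comp <- round(config$complete_fraction * n)
    true_class <- rep("null", n)
    if (n_eff > 0) {
      true_class[seq_len(n_eff)] <-
        rep(c("up", "down"), length.out = n_eff)
    }
    if (n_comp > 0) {
      idx <- n_eff + seq_len(n_comp)
      true_class[idx] <- rep(c("induced_complete", "repressed_complete"),
                             length.out = n_comp)
    }
    true_log2fc <- dplyr::case_when(
      true_class == "up" ~ config$effect_size_log2,
      true_class == "down" ~ -config$effect_size_log2,
      TRUE ~ 0
    )
    baseline <- rlnorm(n, meanlog = log(1e6), sdlog = 1)

    long <- tidyr::expand_grid(
      i = seq_len(n),
      group = c("WT", "dmoeA"),
      replicate = seq_len(reps)
    ) |>
      dplyr::mutate(
        accession = accession[.data$i],
        mu = baseline[.data$i] *
          ifelse(.data$group == "dmoeA", 2^true_log2fc[.data$i], 1),
        abundance = .data$mu * rlnorm(dplyr::n(), 0, config$replicate_sigma),
        abundance = dplyr::case_when(
          true_class[.data$i] == "induced_complete" & .data$group == "WT" ~ NA_real_,
          true_class[.data$i] == "repressed_complete" & .data$group == "dmoeA" ~ NA_real_,
          TRUE ~ .data$abundance
        )
      ) |>
      dplyr::select("accession", "group", "replicate", "abundance")

    list(
      abundance = long,
      truth = tibble::tibble(accession = accession,
                             true_class = true_class,
                             true_log2fc = true_log2fc)
    )
  })
}
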