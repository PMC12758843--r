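#' The eight molybdenum-cofactor pathway genes
#'
#' Canonical gene order of the putative MoCo synthesis operon:
#' moeA, mobA, sumT, moaD, moeZ, moaE, moaC2, moaA.
#'
#' @return Character vector of gene symbols.
#' @export
moco_genes <- function() {
  c("moeA", "mobA", "sumT", "moaD", "moeZ", "moaE", "moaC2", "moaA")
}

check_pa_matrix <- function(matrix, genes) {
  if (!is.data.frame(matrix) || nrow(matrix) == 0) {
    stop_input("presence/absence matrix must be a non-empty data frame")
  }
  missing <- setdiff(c("genome", "class", genes), names(matrix))
  if (length(missing)) {
    stop_input("presence/absence matrix lacks columns: %s",
               paste(missing, collapse = ", "))
  }
  vals <- as.matrix(matrix[genes])
  if (any(is.na(vals)) || !all(vals %in% c(0, 1, TRUE, FALSE))) {
    stop_input("gene columns must be 0/1 with no missing values")
  }
  invisible(matrix)
}

#' Per-gene, per-class presence prevalence
#'
#' Percentage of genomes in each structural-color class that carry each
#' pathway gene, rounded half away from zero to the integer percent (the
#' convention of printed prevalence tables). Empty classes yield `NA`
#' percentages, never 0.
#'
#' @param matrix Data frame with columns `genome`, `class` (e.g. `"SC"` /
#'   `"non-SC"`) and one 0/1 column per gene.
#' @param genes Gene columns to summarize (default [moco_genes()]).
#' @return A tibble with columns `class`, `class_size`, `gene`, `n_present`,
#'   `percent`.
#' @export
#' @examples
#' pa <- make_presence_fixtures()
#' gene_prevalence(dplyr::bind_rows(pa$sc, pa$non_sc))
gene_prevalence <- function(matrix, genes = moco_genes()) {
  check_pa_matrix(matrix, genes)
  matrix |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      class_size = dplyr::n(),
      dplyr::across(dplyr::all_of(genes), ~ sum(as.numeric(.x))),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(dplyr::all_of(genes), names_to = "gene",
                        values_to = "n_present") |>
    dplyr::mutate(
      gene = factor(.data$gene, levels = genes),
      percent = ifelse(.data$class_size > 0,
                       round_half_away(100 * .data$n_present / .data$class_size),
                       NA_real_)
    ) |>
    dplyr::arrange(.data$class, .data$gene)
}

#' Pathway completeness histogram by class
#'
#' Counts genomes in each class by how many pathway genes they lack:
#' 0 missing is a complete pathway; all genes missing is total pathway loss.
#' Per-class counts always sum to the class size.
#'
#' @inheritParams gene_prevalence
#' @return A tibble with columns `class`, `n_missing`, `n_genomes`,
#'   `complete` (logical, `n_missing == 0`) and `all_absent`.
#' @export
#' @examples
#' pathway_completeness(make_presence_fixtures()$sc)
pathway_completeness <- function(matrix, genes = moco_genes()) {
  if (length(genes) == 0) {
    # vacuous pathway: every genome is complete
    return(
      matrix |>
        dplyr::count(.data$class, name = "n_genomes") |>
        dplyr::mutate(n_missing = 0L, complete = TRUE, all_absent = FALSE) |>
        dplyr::select("class", "n_missing", "n_genomes", "complete", "all_absent")
    )
  }
  check_pa_matrix(matrix, genes)
  matrix |>
    dplyr::mutate(
      n_missing = rowSums(1 - as.matrix(dplyr::pick(dplyr::all_of(genes))))
    ) |>
    dplyr::count(.data$class, .data$n_missing, name = "n_genomes") |>
    dplyr::mutate(
      n_missing = as.integer(.data$n_missing),
      complete = .data$n_missing == 0L,
      all_absent = .data$n_missing == length(genes)
    ) |>
    dplyr::arrange(.data$class, .data$n_missing)
}

check_loci <- function(loci) {
  need <- c("contig", "start", "end", "name")
  missing <- setdiff(need, names(loci))
  if (length(missing)) {
    stop_input("loci table lacks columns: %s", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(loci$start)) || any(!is.finite(loci$end)) ||
      any(loci$start < 1) || any(loci$end < loci$start)) {
    stop_input("locus coordinates must be positive with start <= end (1-based inclusive)")
  }
  invisible(loci)
}

#' Cluster gene loci into putative operons by genomic proximity
#'
#' Groups consecutive loci on the same contig whose intervening gap
#' (`next start - previous end - 1`, in bases, using the running maximum end
#' so overlapping genes join) is at most `max_gap_bp`. A contig change always
#' splits. This is the proximity rule used to delimit putative operons and
#' polysaccharide utilization loci: genes separated by stretches longer than
#' 5 kb are treated as distinct clusters. Strand is carried but ignored.
#'
#' @param loci Data frame with columns `contig`, `start`, `end`, `name`
#'   (optionally `strand`); 1-based inclusive coordinates.
#' @param max_gap_bp Maximum intervening gap joining a cluster, bases
#'   (default 5000).
#' @return The loci tibble sorted in genomic order with an integer
#'   `cluster` column; cluster ids increase along the genome.
#' @export
#' @examples
#' loci <- tibble::tibble(
#'   contig = "c1", start = c(1, 1200, 9000), end = c(1000, 2000, 9500),
#'   name = c("a", "b", "c")
#' )
#' cluster_loci(loci)   # a+b cluster together; c is 6999 bp away, separate
cluster_loci <- function(loci, max_gap_bp = 5000) {
  loci <- tibble::as_tibble(loci)
  check_loci(loci)
  assert_scalar_num(max_gap_bp, "max_gap_bp", lower = 0)
  loci |>
    dplyr::arrange(.data$contig, .data$start, .data$end) |>
    dplyr::group_by(.data$contig) |>
    dplyr::mutate(
      .gap = .data$start - dplyr::lag(cummax(.data$end)) - 1,
      .new = dplyr::coalesce(.data$.gap > max_gap_bp, TRUE)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(cluster = cumsum(.data$.new)) |>
    dplyr::select(-".gap", -".new")
}
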