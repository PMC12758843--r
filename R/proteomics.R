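#' Pooled-variance two-group Student's t-test
#'
#' Two-sided Student's t with pooled variance and `n1 + n2 - 2` degrees of
#' freedom, the classical test for triplicate proteomics comparisons. A
#' small variance floor (`var_floor`) keeps the statistic finite when both
#' groups are (numerically) constant, so an unequal pair of constant groups
#' yields p near 0 rather than 0/0.
#'
#' @param x,y Numeric vectors of (log-transformed) abundances, length >= 2
#'   each.
#' @param var_floor Lower bound on the pooled variance (default 1e-12).
#' @return A list with `statistic` (t), `p_value`, `df`.
#' @export
#' @examples
#' two_group_test(c(10, 11, 12), c(13, 14, 15))  # t = -3.674, p = 0.0213
two_group_test <- function(x, y, var_floor = 1e-12) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) {
    stop_input("two_group_test needs >= 2 detected values per group")
  }
  df <- n1 + n2 - 2
  sp2 <- max(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df,
             var_floor)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t, p_value = 2 * pt(-abs(t), df), df = df)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: monotone in the sorted order,
#' capped at 1, ties share a value. `NA` entries (untestable proteins) are
#' excluded from the correction and returned as `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_input("`p` must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Classify the regulation of one protein
#'
#' Applies the thresholded calling rule: a protein is `down` when
#' significant (`p_value < p_cut`) and `log2fc < -fc_cut`, `up` when
#' significant and `log2fc > fc_cut`. Detection-pattern calls override the
#' quantitative rule: a protein found only in the reference strain is
#' `repressed_complete`, only in the mutant `induced_complete`. Untestable
#' proteins (too few detected replicates) are labeled `untestable`;
#' everything else is `unchanged`.
#'
#' @param log2fc log2 fold change (mutant / reference).
#' @param p_value Raw (or BH-adjusted, per the chosen gate) p-value.
#' @param detection `"both"`, `"ref_only"`, `"mut_only"`, `"neither"`, or
#'   `"untestable"`.
#' @param p_cut Significance cut-off (default 0.01).
#' @param fc_cut |log2fc| gate (default 1).
#' @return One of `"up"`, `"down"`, `"unchanged"`, `"repressed_complete"`,
#'   `"induced_complete"`, `"untestable"`.
#' @export
#' @examples
#' classify_regulation(-1.32, 0.001, "both")      # "down"
#' classify_regulation(NA, NA, "ref_only")        # "repressed_complete"
classify_regulation <- function(log2fc, p_value, detection = "both",
                                p_cut = 0.01, fc_cut = 1) {
  if (detection == "ref_only") return("repressed_complete")
  if (detection == "mut_only") return("induced_complete")
  if (detection %in% c("untestable", "neither")) return("untestable")
  if (is.na(p_value) || is.na(log2fc)) return("untestable")
  if (p_value < p_cut && log2fc < -fc_cut) return("down")
  if (p_value < p_cut && log2fc > fc_cut) return("up")
  "unchanged"
}

#' Differential abundance pipeline for a two-strain proteome
#'
#' Runs the full calling procedure on a long-format abundance table:
#' per-protein pooled t-test on log2 abundances, BH correction across
#' testable proteins, fold change from linear-scale group means, and
#' thresholded classification including complete repression/induction by
#' detection pattern. Proteins absent from all replicates of exactly one
#' group bypass the test; proteins with fewer than 2 detected replicates in
#' either group are untestable.
#'
#' @param abundance Long tibble with columns `accession`, `group`,
#'   `replicate`, `abundance` (linear scale, `NA` = not detected).
#' @param ref_group,mut_group The two group labels; fold change is
#'   mutant / reference (default `"WT"` and `"dmoeA"`).
#' @param p_cut,fc_cut Calling thresholds (defaults 0.01 and 1).
#' @param gate `"p"` (default) gates significance on the raw p-value, as in
#'   classical thresholded calling; `"q"` gates on the BH-adjusted value.
#' @return A tibble of regulation calls: `accession`, `mean_ref`,
#'   `mean_mut`, `log2fc`, `t_statistic`, `p_value`, `q_value`, `detection`,
#'   `call`.
#' @export
proteome_de <- function(abundance, ref_group = "WT", mut_group = "dmoeA",
                        p_cut = 0.01, fc_cut = 1, gate = c("p", "q")) {
  gate <- match.arg(gate)
  need <- c("accession", "group", "replicate", "abundance")
  missing <- setdiff(need, names(abundance))
  if (length(missing)) {
    stop_input("abundance table lacks columns: %s",
               paste(missing, collapse = ", "))
  }
  groups <- unique(abundance$group)
  if (!all(c(ref_group, mut_group) %in% groups)) {
    stop_input("abundance table must contain groups '%s' and '%s'",
               ref_group, mut_group)
  }

  per_protein <- abundance |>
    dplyr::filter(.data$group %in% c(ref_group, mut_group)) |>
    tidyr::nest(data = -"accession") |>
    dplyr::mutate(res = purrr::map(.data$data, function(d) {
      xr <- d$abundance[d$group == ref_group]
      xm <- d$abundance[d$group == mut_group]
      det_r <- sum(!is.na(xr)); det_m <- sum(!is.na(xm))
      detection <- dplyr::case_when(
        det_r > 0 && det_m == 0 ~ "ref_only",
        det_m > 0 && det_r == 0 ~ "mut_only",
        det_r == 0 && det_m == 0 ~ "neither",
        det_r >= 2 && det_m >= 2 ~ "both",
        TRUE ~ "untestable"
      )
      mean_ref <- if (det_r > 0) mean(xr, na.rm = TRUE) else NA_real_
      mean_mut <- if (det_m > 0) mean(xm, na.rm = TRUE) else NA_real_
      log2fc <- if (detection == "both") log2(mean_mut / mean_ref) else NA_real_
      if (detection == "both") {
        tt <- two_group_test(log2(xm[!is.na(xm)]), log2(xr[!is.na(xr)]))
        tstat <- tt$statistic; p <- tt$p_value
      } else {
        tstat <- NA_real_; p <- NA_real_
      }
      tibble::tibble(mean_ref = mean_ref, mean_mut = mean_mut,
                     log2fc = log2fc, t_statistic = tstat, p_value = p,
                     detection = detection)
    })) |>
    dplyr::select(-"data") |>
    tidyr::unnest("res")

  per_protein |>
    dplyr::mutate(
      q_value = bh_adjust(.data$p_value),
      call = purrr::pmap_chr(
        list(.data$log2fc,
             if (gate == "p") .data$p_value else .data$q_value,
             .data$detection),
        classify_regulation, p_cut = p_cut, fc_cut = fc_cut
      )
    )
}

#' Filter regulation calls to proteins likely to be secreted
#'
#' Keeps proteins flagged as carrying a signal peptide (Sec substrates) or
#' as non-classically secreted, and reports the two sub-counts and their
#' union. A protein with both flags counts once in the union. Proteins
#' without annotation are dropped with a warning.
#'
#' @param calls Tibble with an `accession` column (typically from
#'   [proteome_de()]).
#' @param annotations Tibble with columns `accession`,
#'   `has_signal_peptide`, `nonclassical_secreted` (logical or 0/1).
#' @return The filtered calls tibble with the two flag columns joined; the
#'   counts are attached as attribute `"secretion_counts"` (a named list
#'   `signal_peptide`, `nonclassical`, `union`).
#' @export
secretion_filter <- function(calls, annotations) {
  need <- c("accession", "has_signal_peptide", "nonclassical_secreted")
  missing <- setdiff(need, names(annotations))
  if (length(missing)) {
    stop_input("annotations lack columns: %s", paste(missing, collapse = ", "))
  }
  unannotated <- setdiff(calls$accession, annotations$accession)
  if (length(unannotated)) {
    warn(sprintf("%d proteins lack annotation and are excluded: %s%s",
                 length(unannotated),
                 paste(head(unannotated, 3), collapse = ", "),
                 if (length(unannotated) > 3) ", ..." else ""))
  }
  joined <- calls |>
    dplyr::inner_join(
      annotations |>
        dplyr::select(dplyr::all_of(need)) |>
        dplyr::mutate(dplyr::across(-"accession", as.logical)),
      by = "accession"
    )
  kept <- joined |>
    dplyr::filter(.data$has_signal_peptide | .data$nonclassical_secreted)
  attr(kept, "secretion_counts") <- list(
    signal_peptide = sum(kept$has_signal_peptide),
    nonclassical = sum(kept$nonclassical_secreted),
    union = nrow(kept)
  )
  kept
}

#' Percentage of a count, printed-table style
#'
#' `100 * part / whole`, rounded half away from zero to one decimal — the
#' convention of proteome bookkeeping sentences ("58.1% (3,181 proteins)").
#' A zero `whole` yields `NA` (undefined), never 0.
#'
#' @param part Numerator count(s), `0 <= part <= whole`.
#' @param whole Denominator count(s).
#' @return Percentage(s) at one-decimal precision.
#' @export
#' @examples
#' summarize_counts(3181, 5471)  # 58.1
#' summarize_counts(909, 1504)   # 60.4
summarize_counts <- function(part, whole) {
  if (any(part < 0 | part > whole, na.rm = TRUE)) {
    stop_input("`part` must satisfy 0 <= part <= whole")
  }
  ifelse(whole > 0, round_half_away(100 * part / whole, 1), NA_real_)
}

#' Overlay regulation calls on genomic clusters
#'
#' Summarizes per-operon regulation: joins calls to clustered loci (by
#' locus name = accession) and reports, per cluster, the member calls, the
#' dominant direction (majority among directional calls, counting complete
#' repression as down and complete induction as up; ties give `"mixed"`, no
#' directional call gives `"none"`), and the fraction of members detected.
#'
#' @param calls Regulation call tibble from [proteome_de()].
#' @param clusters Clustered loci from [cluster_loci()] (columns `cluster`,
#'   `name`, ...).
#' @return A tibble with one row per cluster: `cluster`, `n_members`,
#'   `n_up`, `n_down`, `dominant`, `fraction_detected`, `members` (list
#'   column of per-member calls).
#' @export
overlay_clusters <- function(calls, clusters) {
  if (!"cluster" %in% names(clusters)) {
    stop_input("`clusters` must carry a `cluster` column (see cluster_loci())")
  }
  clusters |>
    dplyr::left_join(
      calls |> dplyr::select("accession", "call"),
      by = c(name = "accession")
    ) |>
    dplyr::mutate(call = dplyr::coalesce(.data$call, "undetected")) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_up = sum(.data$call %in% c("up", "induced_complete")),
      n_down = sum(.data$call %in% c("down", "repressed_complete")),
      dominant = dplyr::case_when(
        n_up == 0 & n_down == 0 ~ "none",
        n_up > n_down ~ "up",
        n_down > n_up ~ "down",
        TRUE ~ "mixed"
      ),
      fraction_detected = mean(!.data$call %in% c("undetected", "untestable")),
      members = list(dplyr::pick("name", "call")),
      .groups = "drop"
    )
}

#' Volcano plot of regulation calls
#'
#' log2 fold change against -log10 p with the calling gates drawn as dashed
#' lines, colored by call.
#'
#' @param calls Regulation call tibble from [proteome_de()].
#' @param p_cut,fc_cut Gates to draw (defaults 0.01 and 1).
#' @return A ggplot object.
#' @export
plot_volcano <- function(calls, p_cut = 0.01, fc_cut = 1) {
  df <- calls |> dplyr::filter(is.finite(.data$log2fc), is.finite(.data$p_value))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$p_value),
                                   color = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-fc_cut, fc_cut), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_cut), linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(
      up = "#d73027", down = "#4575b4", unchanged = "grey60",
      untestable = "grey85"
    ), na.value = "grey85") +
    ggplot2::labs(x = "log2 fold change (mutant / reference)",
                  y = "-log10 p") +
    ggplot2::theme_minimal()
}
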