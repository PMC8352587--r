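#' Collect junction evidence from discordantly assigned read pairs
#'
#' A pair contributes evidence when exactly one mate is genome-unique and the
#' other is TE-assigned (the classic discordant signature of a non-reference
#' insertion). With an FR library, a genome mate on the `+` strand points
#' rightward into the insertion, so it anchors the LEFT side of the junction
#' (anchor = its end coordinate, half-open); a genome mate on the `-` strand
#' anchors the RIGHT side (anchor = its start coordinate). Anchors are the
#' innermost genome coordinates, so for perfect data the innermost left and
#' right anchors converge on the junction.
#'
#' @param assignments an [assign_reads()] tibble of paired reads (`mate`
#'   column set; two rows per `read_id`).
#' @return tibble of class `junction_evidence`: `pair_id`, `chrom`, `side`
#'   (`left`/`right`), `anchor` (0-based), `family`, `te_strand`, `te_pos`,
#'   `genome_strand`; attribute `n_skipped` counts pairs without the
#'   discordant signature.
#' @export
collect_evidence <- function(assignments) {
  wide <- assignments |>
    dplyr::filter(!is.na(.data$mate)) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::filter(dplyr::n() == 2L) |>
    dplyr::ungroup()
  n_pairs <- length(unique(wide$read_id))

  g <- dplyr::filter(wide, .data$category == "GENOME")
  t <- dplyr::filter(wide, .data$category == "TE")
  ev <- dplyr::inner_join(
    g |> dplyr::select("read_id", chrom = "target", g_pos = "pos",
                       genome_strand = "strand", g_len = "len"),
    t |> dplyr::select("read_id", family = "target", te_pos = "pos",
                       te_strand = "strand"),
    by = "read_id")

  out <- ev |>
    dplyr::transmute(
      pair_id = .data$read_id,
      chrom = .data$chrom,
      side = ifelse(.data$genome_strand == "+", "left", "right"),
      anchor = ifelse(.data$genome_strand == "+",
                      .data$g_pos + .data$g_len, .data$g_pos),
      family = .data$family,
      te_strand = .data$te_strand,
      te_pos = .data$te_pos,
      genome_strand = .data$genome_strand) |>
    dplyr::arrange(.data$chrom, .data$family, .data$anchor)
  attr(out, "n_skipped") <- n_pairs - nrow(out)
  class(out) <- c("junction_evidence", class(out))
  out
}

# directionality vote for one evidence cluster: '+' iff the TE mate's
# consensus strand is opposite the side (left mates read into the element's
# 5' end when the element is sense-inserted)
strand_votes <- function(side, te_strand) {
  ifelse((side == "left" & te_strand == "-") |
           (side == "right" & te_strand == "+"), "+", "-")
}

majority_strand <- function(side, te_strand) {
  v <- strand_votes(side, te_strand)
  n_plus <- sum(v == "+")
  n_minus <- sum(v == "-")
  if (n_plus > n_minus) "+" else if (n_minus > n_plus) "-" else "."
}

#' Infer the strand of an insertion from its evidence cluster
#'
#' Majority vote over per-record directionality votes: a record votes `+`
#' iff (left side and TE mate on the consensus `-` strand) or (right side
#' and TE mate on `+`). An exact tie yields `"."`.
#'
#' @param evidence tibble with `side` and `te_strand` columns (one cluster).
#' @return `"+"`, `"-"` or `"."`.
#' @export
infer_strand <- function(evidence) {
  if (nrow(evidence) == 0L) abort("empty evidence cluster")
  majority_strand(evidence$side, evidence$te_strand)
}

#' Cluster junction evidence and call insertions (1p1 filter)
#'
#' Per (chromosome, family), anchors are clustered by single linkage with
#' gap <= `max_gap`; a cluster becomes a call iff it is supported by at least
#' `min_support_per_side` records on EACH side of the junction (the
#' both-sides "1p1" rule). The junction interval is
#' `[innermost left anchor, innermost right anchor)`, clamped to
#' non-negative length.
#'
#' @param evidence a [collect_evidence()] tibble.
#' @param max_gap single-linkage gap (bp, > 0); a sensible default is the
#'   mean fragment length + 3 fragment SDs.
#' @param min_support_per_side minimum evidence records per side (default 1).
#' @return tibble of class `insertion_calls`: `chrom`, `start`, `end`,
#'   `family`, `strand`, `support_left`, `support_right`, `midpoint`,
#'   `source = "called"`.
#' @export
cluster_and_call <- function(evidence, max_gap, min_support_per_side = 1L) {
  if (max_gap <= 0) abort("max_gap must be > 0")
  empty <- tibble(
    chrom = character(0), start = integer(0), end = integer(0),
    family = character(0), strand = character(0),
    support_left = integer(0), support_right = integer(0),
    midpoint = integer(0), source = character(0))
  if (nrow(evidence) == 0L) {
    class(empty) <- c("insertion_calls", class(empty))
    return(empty)
  }
  calls <- evidence |>
    dplyr::arrange(.data$chrom, .data$family, .data$anchor) |>
    dplyr::group_by(.data$chrom, .data$family) |>
    dplyr::mutate(cluster = cumsum(
      c(1L, as.integer(diff(.data$anchor) > max_gap)))) |>
    dplyr::group_by(.data$chrom, .data$family, .data$cluster) |>
    dplyr::summarise(
      support_left = sum(.data$side == "left"),
      support_right = sum(.data$side == "right"),
      la = if (any(.data$side == "left"))
        max(.data$anchor[.data$side == "left"]) else NA_integer_,
      ra = if (any(.data$side == "right"))
        min(.data$anchor[.data$side == "right"]) else NA_integer_,
      strand = majority_strand(.data$side, .data$te_strand),
      .groups = "drop") |>
    dplyr::filter(.data$support_left >= min_support_per_side,
                  .data$support_right >= min_support_per_side) |>
    dplyr::mutate(
      start = pmin(.data$la, .data$ra),
      end = pmax(.data$la, .data$ra),
      midpoint = as.integer(floor((.data$start + .data$end) / 2)),
      source = "called") |>
    dplyr::select("chrom", "start", "end", "family", "strand",
                  "support_left", "support_right", "midpoint", "source") |>
    dplyr::arrange(.data$chrom, .data$start)
  class(calls) <- c("insertion_calls", class(calls))
  calls
}

#' Default clustering gap from the WGS fragment model
#'
#' All junction-spanning anchors of one insertion fall within roughly one
#' fragment span, so the default is `fragment_mean + 3 * fragment_sd`.
#'
#' @param cfg a [sim_config()] (uses its `wgs` block), or a list with
#'   `fragment_mean` and `fragment_sd`.
#' @return gap in bp.
#' @export
default_max_gap <- function(cfg) {
  w <- if (inherits(cfg, "sim_config")) cfg$wgs else cfg
  w$fragment_mean + 3 * w$fragment_sd
}

#' Compare called insertions with a truth set
#'
#' Greedy 1-to-1 matching: candidate (call, truth) pairs of the same family
#' on the same chromosome within `position_tolerance` (by junction point
#' distance) are matched closest-first. Precision is `NA` when there are no
#' calls.
#'
#' @param calls a [cluster_and_call()] tibble (uses `midpoint`).
#' @param truth tibble with `chrom`, `pos`, `family`, `strand` (e.g. the
#'   `insertions` table of a [build_genome()] result).
#' @param position_tolerance maximum junction distance (bp) for a match.
#' @return one-row tibble: `n_calls`, `n_truth`, `n_matched`, `precision`,
#'   `recall`, `median_position_error`, `strand_accuracy`.
#' @export
evaluate_calls <- function(calls, truth, position_tolerance = 50) {
  n_calls <- nrow(calls)
  n_truth <- nrow(truth)
  if (n_calls == 0L || n_truth == 0L) {
    return(tibble(
      n_calls = n_calls, n_truth = n_truth, n_matched = 0L,
      precision = if (n_calls == 0L) NA_real_ else 0,
      recall = if (n_truth == 0L) NA_real_ else 0,
      median_position_error = NA_real_, strand_accuracy = NA_real_))
  }
  pairs <- tidyr::crossing(ci = seq_len(n_calls), ti = seq_len(n_truth)) |>
    dplyr::filter(calls$chrom[.data$ci] == truth$chrom[.data$ti],
                  calls$family[.data$ci] == truth$family[.data$ti]) |>
    dplyr::mutate(dist = abs(calls$midpoint[.data$ci] - truth$pos[.data$ti])) |>
    dplyr::filter(.data$dist <= position_tolerance) |>
    dplyr::arrange(.data$dist)
  used_c <- logical(n_calls); used_t <- logical(n_truth)
  matched <- list()
  for (i in seq_len(nrow(pairs))) {
    ci <- pairs$ci[i]; ti <- pairs$ti[i]
    if (!used_c[ci] && !used_t[ti]) {
      used_c[ci] <- TRUE; used_t[ti] <- TRUE
      matched[[length(matched) + 1L]] <- pairs[i, ]
    }
  }
  m <- dplyr::bind_rows(matched)
  n_m <- nrow(m)
  tibble(
    n_calls = n_calls, n_truth = n_truth, n_matched = n_m,
    precision = n_m / n_calls,
    recall = n_m / n_truth,
    median_position_error = if (n_m) median(m$dist) else NA_real_,
    strand_accuracy = if (n_m)
      mean(calls$strand[m$ci] == truth$strand[m$ti]) else NA_real_)
}

#' End-to-end insertion discovery from simulated WGS
#'
#' Convenience wrapper: assign both mates with the two-tier policy, collect
#' discordant-pair evidence, cluster and apply the 1p1 filter.
#'
#' @param wgs a [simulate_wgs()] result.
#' @param te_index,genome_index [build_index()] objects (genome index over
#'   the REFERENCE genome).
#' @param max_gap see [cluster_and_call()].
#' @param min_support_per_side see [cluster_and_call()].
#' @param max_mismatches,seed passed to [assign_reads()].
#' @return list with `assignments`, `evidence`, `calls`.
#' @export
call_insertions <- function(wgs, te_index, genome_index, max_gap,
                            min_support_per_side = 1L, max_mismatches = 2L,
                            seed = 1L) {
  asn <- assign_reads(wgs$reads, te_index, genome_index,
                      max_mismatches = max_mismatches, seed = seed)
  ev <- collect_evidence(asn)
  list(assignments = asn, evidence = ev,
       calls = cluster_and_call(ev, max_gap = max_gap,
                                min_support_per_side = min_support_per_side))
}
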