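#' Build an rpm-scaled binned coverage track from genome assignments
#'
#' Each GENOME-assigned read adds its per-base overlap to the bins it spans;
#' bin values are `overlap_bases / bin_length * 1e6 / library_total`, i.e.
#' mean read depth in the bin on the reads-per-million scale. The final
#' partial bin is normalised by its true length. Reads running past the
#' chromosome end are clipped (counted in attribute `n_clipped`).
#'
#' @param assignments an [assign_reads()] tibble (GENOME rows are used).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param bin_size bin width in bp (default 10).
#' @param library_total rpm denominator; defaults to the number of TE +
#'   GENOME assigned reads in `assignments`.
#' @return object of class `coverage_track`: list with `values` (named list
#'   of per-chromosome bin vectors), `bin_size`, `library_total`,
#'   `chrom_lengths`.
#' @export
coverage_track <- function(assignments, chrom_lengths, bin_size = 10L,
                           library_total = NULL) {
  library_total <- library_total %||%
    sum(assignments$category != "UNMAPPED")
  if (is.null(library_total) || library_total <= 0)
    abort("library_total must be > 0")
  g <- dplyr::filter(assignments, .data$category == "GENOME",
                     .data$target %in% names(chrom_lengths))
  n_clipped <- 0L
  values <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    nb <- ceiling(L / bin_size)
    gi <- g[g$target == ch, ]
    if (nrow(gi) == 0L) return(numeric(nb))
    s <- pmax(gi$pos, 0L)
    e <- gi$pos + gi$len
    n_clipped <<- n_clipped + sum(e > L)
    e <- pmin(e, L)
    # per-base depth via difference array, then bin sums via cumsum
    d <- numeric(L + 1L)
    add <- tapply(rep(1L, length(s)), s + 1L, sum)
    d[as.integer(names(add))] <- d[as.integer(names(add))] + add
    sub <- tapply(rep(1L, length(e)), pmin(e + 1L, L + 1L), sum)
    d[as.integer(names(sub))] <- d[as.integer(names(sub))] - sub
    cov <- cumsum(d[seq_len(L)])
    cs <- c(0, cumsum(cov))
    ends <- pmin(seq_len(nb) * bin_size, L)
    starts <- (seq_len(nb) - 1L) * bin_size
    (cs[ends + 1L] - cs[starts + 1L]) / (ends - starts) *
      1e6 / library_total
  })
  names(values) <- names(chrom_lengths)
  if (n_clipped > 0)
    warning(n_clipped, " reads clipped at chromosome ends")
  structure(list(values = values, bin_size = as.integer(bin_size),
                 library_total = library_total,
                 chrom_lengths = chrom_lengths,
                 n_clipped = n_clipped),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> bin_size ", x$bin_size, " bp, ",
      length(x$values), " chromosomes, library_total ",
      x$library_total, "\n", sep = "")
  invisible(x)
}

#' Pool replicate tracks
#'
#' Averages bin values of tracks built on the same genome/bin grid, mirroring
#' track construction on concatenated replicates (visualisation use; keep
#' replicates separate for statistics).
#'
#' @param tracks list of [coverage_track()] objects.
#' @return a `coverage_track`.
#' @export
pool_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  out <- tracks[[1L]]
  for (ch in names(out$values)) {
    m <- sapply(tracks, function(t) t$values[[ch]])
    out$values[[ch]] <- rowMeans(m)
  }
  out$library_total <- mean(vapply(tracks, `[[`, 1, "library_total"))
  out
}

#' Windowed IP/input enrichment
#'
#' Window means of the IP and input rpm tracks, then
#' `E = log2((ip + psi) / (input + psi))` with pseudocount `psi`.
#'
#' @param ip,input [coverage_track()] objects on the same bin grid.
#' @param window window size in bp (default 10000).
#' @param step step between window starts; defaults to `window`
#'   (non-overlapping).
#' @param psi pseudocount in rpm units (default 0.5).
#' @return tibble `chrom`, `start`, `end`, `ip`, `input`, `enrichment`.
#' @export
window_enrichment <- function(ip, input, window = 10000L, step = window,
                              psi = 0.5) {
  if (!identical(names(ip$values), names(input$values)) ||
      ip$bin_size != input$bin_size)
    abort("ip and input tracks must share chromosomes and bin size")
  bs <- ip$bin_size
  res <- lapply(names(ip$values), function(ch) {
    L <- ip$chrom_lengths[[ch]]
    starts <- seq(0L, max(0L, L - 1L), by = step)
    ends <- pmin(starts + window, L)
    i0 <- floor(starts / bs) + 1L
    i1 <- ceiling(ends / bs)
    ipv <- ip$values[[ch]]; inv <- input$values[[ch]]
    ipm <- vapply(seq_along(starts), function(j) mean(ipv[i0[j]:i1[j]]), 1)
    inm <- vapply(seq_along(starts), function(j) mean(inv[i0[j]:i1[j]]), 1)
    tibble(chrom = ch, start = starts, end = ends, ip = ipm, input = inm)
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(enrichment = log2((.data$ip + psi) / (.data$input + psi)))
}

#' Call euchromatic regions from enrichment windows
#'
#' Maximal runs of consecutive windows with enrichment below `tau` are merged
#' into euchromatic intervals; the complement is heterochromatic. Raising
#' `tau` never shrinks the euchromatic set.
#'
#' @param windows a [window_enrichment()] tibble.
#' @param tau log2 enrichment threshold (default `log2(2)`, i.e. 2-fold).
#' @return tibble `chrom`, `start`, `end` of euchromatic regions.
#' @export
call_euchromatin <- function(windows, tau = log2(2)) {
  if (!any(windows$enrichment < tau)) {
    return(tibble(chrom = character(0), start = integer(0),
                  end = integer(0)))
  }
  windows |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(
      eu = .data$enrichment < tau,
      run = cumsum(c(TRUE, diff(as.integer(.data$eu)) != 0L) |
                     c(TRUE, .data$end[-dplyr::n()] < .data$start[-1L]))) |>
    dplyr::filter(.data$eu) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::select("chrom", "start", "end") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Insertion-centric oriented signal matrix
#'
#' One row per insertion: track bin values in `[mid - flank, mid + flank)`
#' around the junction midpoint, with the column order reversed for `-`
#' strand insertions so that increasing column index always means downstream
#' of the element's 5'->3' direction. Positions outside the chromosome are
#' `NA` (excluded from column statistics). Columns are snapped to the track's
#' bin grid.
#'
#' @param track a [coverage_track()].
#' @param insertions tibble with `chrom`, `strand`, and either `midpoint`, or
#'   `pos`, or `start`/`end` (junction interval); rows on unknown
#'   chromosomes are skipped with a warning.
#' @param flank half-width in bp (multiple of the track bin size;
#'   default 10000).
#' @return object of class `signal_matrix`: list with `matrix`
#'   (insertions x bins), `insertions` (row metadata tibble), `bin_size`,
#'   `flank`.
#' @export
insertion_matrix <- function(track, insertions, flank = 10000L) {
  bs <- track$bin_size
  if (flank %% bs != 0L) abort("flank must be a multiple of the bin size")
  ins <- tibble::as_tibble(insertions)
  if (!"midpoint" %in% names(ins)) {
    ins$midpoint <- if ("pos" %in% names(ins)) ins$pos
      else as.integer(floor((ins$start + ins$end) / 2))
  }
  if (!"id" %in% names(ins))
    ins$id <- paste0("ins", seq_len(nrow(ins)))
  known <- ins$chrom %in% names(track$values)
  if (any(!known)) {
    warning(sum(!known), " insertions on unknown chromosomes skipped")
    ins <- ins[known, ]
  }
  ncol_m <- as.integer(2L * flank / bs)
  mat <- matrix(NA_real_, nrow = nrow(ins), ncol = ncol_m,
                dimnames = list(ins$id, NULL))
  for (i in seq_len(nrow(ins))) {
    v <- track$values[[ins$chrom[i]]]
    idx <- floor((ins$midpoint[i] - flank) / bs) + seq_len(ncol_m)
    ok <- idx >= 1L & idx <= length(v)
    row <- rep(NA_real_, ncol_m)
    row[ok] <- v[idx[ok]]
    if (identical(ins$strand[i], "-")) row <- rev(row)
    mat[i, ] <- row
  }
  structure(list(matrix = mat, insertions = ins, bin_size = bs,
                 flank = as.integer(flank)),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("<signal_matrix> ", nrow(x$matrix), " insertions x ", ncol(x$matrix),
      " bins (", x$bin_size, " bp, +/-", x$flank, " bp)\n", sep = "")
  invisible(x)
}

#' Column-wise metaprofile of a signal matrix
#'
#' @param sm a [insertion_matrix()] result.
#' @return tibble `offset` (bp of bin start relative to the junction),
#'   `mean`, `sd`, `n` (`NA` cells masked).
#' @export
metaprofile <- function(sm) {
  if (nrow(sm$matrix) == 0L) abort("empty signal matrix")
  m <- sm$matrix
  tibble(
    offset = seq(-sm$flank, sm$flank - sm$bin_size, by = sm$bin_size),
    mean = apply(m, 2L, mean, na.rm = TRUE),
    sd = apply(m, 2L, sd, na.rm = TRUE),
    n = apply(m, 2L, function(col) sum(!is.na(col))))
}

#' Downstream/upstream asymmetry scores
#'
#' For each oriented row, `ratio = (mean downstream + psi) /
#' (mean upstream + psi)`; downstream is the right half of the row (the
#' element's 3' side). A ratio above 1 means the signal trails the direction
#' of transcription.
#'
#' @param sm a [insertion_matrix()] result (or a single numeric row vector).
#' @param psi pseudocount in rpm (default 0.5).
#' @return tibble `id`, `family` (if present), `ratio`.
#' @export
asymmetry_score <- function(sm, psi = 0.5) {
  if (is.numeric(sm)) {
    sm <- list(matrix = matrix(sm, nrow = 1, dimnames = list("row1", NULL)),
               insertions = tibble(id = "row1"))
  }
  m <- sm$matrix
  half <- ncol(m) / 2L
  up <- m[, seq_len(half), drop = FALSE]
  down <- m[, half + seq_len(half), drop = FALSE]
  out <- tibble(
    id = rownames(m) %||% paste0("row", seq_len(nrow(m))),
    ratio = unname((rowMeans(down, na.rm = TRUE) + psi) /
                     (rowMeans(up, na.rm = TRUE) + psi)))
  if ("family" %in% names(sm$insertions)) out$family <- sm$insertions$family
  out
}

#' Mean signal over regions per replicate, with a between-condition t-test
#'
#' Computes each replicate track's base-weighted mean rpm over a region set,
#' then compares the two condition groups with a Welch unpaired t-test.
#' Degenerate inputs (zero variance in both groups) report p = 1 for equal
#' means and p = 0 (with `degenerate = TRUE`) for unequal means.
#'
#' @param tracks named list of [coverage_track()] replicates.
#' @param regions tibble `chrom`, `start`, `end` (0-based half-open).
#' @param groups named character/factor, condition per replicate (two
#'   levels required for the test; may be omitted to get means only).
#' @return list of class `region_signal`: `replicates` (tibble `replicate`,
#'   `group`, `mean_rpm`) and `test` (one-row tibble or `NULL`).
#' @export
region_mean_signal <- function(tracks, regions, groups = NULL) {
  mean_one <- function(track) {
    tot <- 0; nb <- 0
    for (i in seq_len(nrow(regions))) {
      ch <- regions$chrom[i]
      if (!ch %in% names(track$values)) next
      bs <- track$bin_size
      v <- track$values[[ch]]
      i0 <- floor(regions$start[i] / bs) + 1L
      i1 <- min(ceiling(regions$end[i] / bs), length(v))
      tot <- tot + sum(v[i0:i1])
      nb <- nb + (i1 - i0 + 1L)
    }
    if (nb == 0) NA_real_ else tot / nb
  }
  reps <- tibble(
    replicate = names(tracks) %||% paste0("rep", seq_along(tracks)),
    mean_rpm = unname(vapply(tracks, mean_one, 1)))
  test <- NULL
  if (!is.null(groups)) {
    reps$group <- if (!is.null(names(groups)))
      as.character(groups[reps$replicate]) else as.character(groups)
    lv <- unique(reps$group)
    if (length(lv) == 2L) {
      x <- reps$mean_rpm[reps$group == lv[1L]]
      y <- reps$mean_rpm[reps$group == lv[2L]]
      if (length(x) >= 2L && length(y) >= 2L) {
        degenerate <- sd(x) == 0 && sd(y) == 0
        if (degenerate) {
          p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
          test <- tibble(group1 = lv[1L], group2 = lv[2L],
                         mean1 = mean(x), mean2 = mean(y),
                         statistic = NA_real_, p_value = p,
                         degenerate = TRUE)
        } else {
          tt <- t.test(x, y)
          test <- tibble(group1 = lv[1L], group2 = lv[2L],
                         mean1 = mean(x), mean2 = mean(y),
                         statistic = unname(tt$statistic),
                         p_value = tt$p.value, degenerate = FALSE)
        }
      }
    }
  }
  structure(list(replicates = reps, test = test), class = "region_signal")
}

#' Flanking regions around insertion junctions
#'
#' Convenience builder for region sets like "euchromatic family-X loci":
#' `[pos - flank, pos + flank)` windows around junction points.
#'
#' @param insertions tibble with `chrom` and `pos` (or `midpoint`).
#' @param flank half-width in bp.
#' @return tibble `chrom`, `start`, `end`.
#' @export
insertion_flanks <- function(insertions, flank = 2000L) {
  pos <- if ("pos" %in% names(insertions)) insertions$pos
    else insertions$midpoint
  tibble(chrom = insertions$chrom,
         start = pmax(0L, pos - as.integer(flank)),
         end = pos + as.integer(flank))
}
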