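#' Reverse complement of a DNA string
#'
#' @param x character scalar over `A`, `C`, `G`, `T` (ambiguity codes are
#'   complemented positionally but never match during search).
#' @return character scalar, the reverse complement.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}

#' Build a tiled k-mer index of a host genome
#'
#' Indexes every genome position `p` with `p %% step_size == 0` (0-based) and
#' `p + tile_size <= length` by its `tile_size`-mer, on the plus strand of each
#' target sequence. Minus-strand hits are found by querying the reverse
#' complement of the probe against this plus-strand index, so the index itself
#' covers both strands implicitly.
#'
#' The default `step_size = 1` indexes every position; together with query
#' tiles taken from both ends of the probe this guarantees (by pigeonhole)
#' that no placement with at most one mismatch is missed. Larger steps (e.g.
#' the classic seeding value 7) are accepted and faster to build, but seeding
#' then becomes heuristic: a single mismatch can dirty every stepped tile a
#' window exposes, so [find_hits()] is only guaranteed exhaustive at step 1.
#'
#' @param genome named character vector of uppercase sequences (a single
#'   unnamed sequence is given the id `"seq1"`), as returned by [read_fasta()].
#' @param tile_size tile length in bases (default 12).
#' @param step_size spacing between indexed genome positions (default 1).
#' @return an object of class `seed_index`.
#' @export
build_seed_index <- function(genome, tile_size = 12L, step_size = 1L) {
  genome <- as_genome(genome)
  if (sum(nchar(genome)) == 0L) stop("empty genome: nothing to index")
  tile_size <- as.integer(tile_size)
  step_size <- as.integer(step_size)
  stopifnot(tile_size >= 1L, step_size >= 1L)
  targets <- lapply(genome, function(seq) {
    n <- nchar(seq)
    if (tile_size > n) {
      env <- new.env(hash = TRUE, parent = emptyenv())
    } else {
      starts <- seq.int(0L, n - tile_size, by = step_size)
      tiles <- substring(seq, starts + 1L, starts + tile_size)
      env <- list2env(split(starts, tiles),
                      envir = new.env(hash = TRUE, parent = emptyenv(),
                                      size = max(length(starts), 1L)))
    }
    list(tiles = env, length = n)
  })
  structure(list(targets = targets, tile_size = tile_size,
                 step_size = step_size),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("seed_index: %d target(s), tile_size=%d, step_size=%d\n",
              length(x$targets), x$tile_size, x$step_size))
  invisible(x)
}

# Coerce genome input (character vector or DNAStringSet) to a named uppercase
# character vector.
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  stopifnot(is.character(genome))
  genome <- toupper(genome)
  if (is.null(names(genome))) {
    names(genome) <- if (length(genome) == 1L) "seq1" else
      paste0("seq", seq_along(genome))
  }
  genome
}

empty_hits <- function() {
  data.frame(probe_id = character(), target_id = character(),
             start = integer(), strand = character(),
             mismatches = integer(), stringsAsFactors = FALSE)
}

# Hamming distance between equal-length strings, capped scanning not needed at
# these sizes.
hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

sort_hits <- function(hits) {
  hits <- unique(hits)
  hits[order(hits$target_id, hits$start, hits$strand), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Find all exact-or-near placements of a probe on a genome (seed and extend)
#'
#' Reports every ungapped placement of `probe` on either strand of the genome
#' whose Hamming distance is at most `max_mismatches` (default 1: the
#' "100% identity or a single base mismatch" hit criterion). Coordinates are
#' 0-based half-open on the plus strand of the target; a minus-strand hit is
#' reported at the plus-strand coordinates of the matched window.
#'
#' Seeding takes exact `tile_size`-mers from both ends of the query (offsets 0
#' and `probe_len - tile_size`); with a step-1 index these two disjoint tiles
#' cannot both contain a single mismatch, so no qualifying placement is missed.
#' When the two query tiles would overlap (`2 * tile_size > probe_len`) the
#' pigeonhole argument fails and the function falls back to an exhaustive
#' window scan.
#'
#' @param probe character scalar, the probe sequence. Probes containing
#'   letters outside `A/C/G/T` (e.g. `N`) yield zero hits with a warning.
#' @param index a `seed_index` from [build_seed_index()].
#' @param genome the genome the index was built from.
#' @param max_mismatches maximum Hamming distance (default 1).
#' @param probe_id id recorded in the output (default `"probe"`).
#' @return data.frame with columns `probe_id`, `target_id`, `start`, `strand`,
#'   `mismatches`, sorted by (target, start, strand) and deduplicated.
#' @seealso [brute_force_hits()] for the exhaustive-scan oracle.
#' @export
find_hits <- function(probe, index, genome, max_mismatches = 1L,
                      probe_id = "probe") {
  stopifnot(inherits(index, "seed_index"))
  genome <- as_genome(genome)
  probe <- toupper(probe)
  if (grepl("[^ACGT]", probe)) {
    warning(sprintf("probe '%s' contains non-ACGT letters; reported as zero hits",
                    probe_id))
    return(empty_hits())
  }
  L <- nchar(probe)
  tile <- index$tile_size
  if (2L * tile > L || index$step_size > 1L) {
    # no completeness guarantee from the seeding scheme: exhaustive fallback
    # only when tiles overlap; a stepped index is honoured as-is (heuristic)
    if (2L * tile > L)
      return(brute_force_hits(probe, genome, max_mismatches, probe_id))
  }
  out <- list()
  k <- 0L
  for (ti in seq_along(index$targets)) {
    tgt_id <- names(index$targets)[ti]
    tgt <- index$targets[[ti]]
    seq <- if (tgt_id %in% names(genome)) genome[[tgt_id]] else NA_character_
    if (is.na(seq) || tgt$length != nchar(seq))
      stop("genome does not match the index (target '", tgt_id, "')")
    nwin <- tgt$length - L + 1L
    if (nwin < 1L) next
    for (strand in c("+", "-")) {
      q <- if (strand == "+") probe else revcomp(probe)
      offsets <- unique(c(0L, L - tile))
      cand <- integer()
      for (o in offsets) {
        qtile <- substr(q, o + 1L, o + tile)
        pos <- tgt$tiles[[qtile]]
        if (!is.null(pos)) cand <- c(cand, pos - o)
      }
      cand <- unique(cand[cand >= 0L & cand <= nwin - 1L])
      for (s in cand) {
        mm <- hamming(q, substr(seq, s + 1L, s + L))
        if (mm <= max_mismatches) {
          k <- k + 1L
          out[[k]] <- list(tgt_id, s, strand, mm)
        }
      }
    }
  }
  if (k == 0L) return(empty_hits())
  hits <- data.frame(
    probe_id = probe_id,
    target_id = vapply(out, `[[`, "", 1L),
    start = vapply(out, function(h) as.integer(h[[2L]]), 0L),
    strand = vapply(out, `[[`, "", 3L),
    mismatches = vapply(out, function(h) as.integer(h[[4L]]), 0L),
    stringsAsFactors = FALSE
  )
  sort_hits(hits)
}

#' Exhaustive-window oracle for probe placement
#'
#' Scans every window on both strands and reports placements within
#' `max_mismatches` Hamming distance. Same output contract as [find_hits()];
#' used as the independent correctness oracle for the seeded matcher and for
#' rejection sampling on tiny designs.
#'
#' @inheritParams find_hits
#' @param genome named character vector of target sequences.
#' @return data.frame as in [find_hits()].
#' @export
brute_force_hits <- function(probe, genome, max_mismatches = 1L,
                             probe_id = "probe") {
  genome <- as_genome(genome)
  probe <- toupper(probe)
  if (grepl("[^ACGT]", probe)) {
    warning(sprintf("probe '%s' contains non-ACGT letters; reported as zero hits",
                    probe_id))
    return(empty_hits())
  }
  L <- nchar(probe)
  res <- list()
  for (tgt_id in names(genome)) {
    seq <- genome[[tgt_id]]
    n <- nchar(seq)
    nwin <- n - L + 1L
    if (nwin < 1L) next
    gch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") probe else revcomp(probe)
      qch <- strsplit(q, "", fixed = TRUE)[[1L]]
      mm <- integer(nwin)
      for (j in seq_len(L)) {
        mm <- mm + (gch[j:(j + nwin - 1L)] != qch[j])
      }
      starts <- which(mm <= max_mismatches) - 1L
      if (length(starts)) {
        res[[length(res) + 1L]] <- data.frame(
          probe_id = probe_id, target_id = tgt_id, start = starts,
          strand = strand, mismatches = mm[starts + 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(empty_hits())
  sort_hits(do.call(rbind, res))
}

#' Match a probe table against a genome
#'
#' Runs [find_hits()] for every probe in a probe table and binds the results.
#'
#' @param probes data.frame with columns `probe_id`, `sequence`.
#' @param genome genome sequences; an index is built if not supplied.
#' @param index optional pre-built `seed_index`.
#' @param max_mismatches maximum Hamming distance per placement (default 1).
#' @return data.frame of hits (possibly zero rows) across all probes.
#' @export
match_probes <- function(probes, genome, index = NULL, max_mismatches = 1L) {
  probes <- validate_probe_table(probes)
  genome <- as_genome(genome)
  if (is.null(index)) index <- build_seed_index(genome)
  hits <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    hits[[i]] <- find_hits(probes$sequence[i], index, genome,
                           max_mismatches = max_mismatches,
                           probe_id = probes$probe_id[i])
  }
  out <- do.call(rbind, c(hits, list(empty_hits())))
  rownames(out) <- NULL
  out
}

#' Validate a probe table
#'
#' Checks unique probe ids and equal-length sequences (default designs use
#' 25-mers).
#'
#' @param probes data.frame with columns `probe_id`, `sequence`.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validate_probe_table <- function(probes) {
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "sequence") %in% names(probes)))
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe ids in probe table")
  if (length(unique(nchar(probes$sequence))) > 1L)
    stop("probe sequences must all have the same length")
  probes
}
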