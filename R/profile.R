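#' Count distinct retained oligos per probe set and chromosome
#'
#' Each oligo contributes at most 1 to a chromosome regardless of how many
#' retained hits it has there, but may contribute to several chromosomes.
#' Every library probe set and every genome chromosome appears in the
#' result even with zero counts.
#'
#' @param aln an `alignment_set` from [screen_library()].
#' @return A `count_matrix` (probe sets x chromosomes).
#' @export
count_per_chromosome <- function(aln) {
    stopifnot(inherits(aln, "alignment_set"))
    sets <- names(aln$set_sizes)
    chroms <- names(aln$chrom_lengths)
    m <- matrix(0L, length(sets), length(chroms),
                dimnames = list(sets, chroms))
    h <- aln$hits
    if (nrow(h)) {
        u <- unique(h[, c("probe_set", "chrom", "oligo_id")])
        tab <- table(factor(u$probe_set, sets), factor(u$chrom, chroms))
        m[] <- as.integer(tab)
    }
    count_matrix(m)
}

#' Minimum and maximum cells of a count matrix
#'
#' @param m a `count_matrix`.
#' @return List with `min_value`, `min_cells`, `max_value`, `max_cells`;
#'   the `*_cells` entries are data frames of (probe_set, chrom) labels,
#'   ties in row-label then column-label order.
#' @export
matrix_extrema <- function(m) {
    if (length(m) == 0) stopf("count matrix is empty")
    locate <- function(v) {
        idx <- which(m == v, arr.ind = TRUE)
        df <- data.frame(probe_set = rownames(m)[idx[, 1]],
                         chrom = colnames(m)[idx[, 2]],
                         stringsAsFactors = FALSE)
        df <- df[order(match(df$probe_set, rownames(m)),
                       match(df$chrom, colnames(m))), , drop = FALSE]
        rownames(df) <- NULL
        df
    }
    list(min_value = min(m), min_cells = locate(min(m)),
         max_value = max(m), max_cells = locate(max(m)))
}

#' Bin retained hits into fixed-width windows
#'
#' A hit is assigned to the window containing its start coordinate.  The
#' last window of each chromosome may be shorter than `window_bp`.  No
#' per-oligo deduplication is applied: every retained locus counts, so
#' per-chromosome window sums can exceed the distinct-oligo count matrix
#' cell.
#'
#' @param aln an `alignment_set`.
#' @param window_bp window width in bp (default 500 kb).
#' @return A [density_profile()] covering every (probe set, chromosome,
#'   window), zeros included.
#' @export
bin_density <- function(aln, window_bp = 500000L) {
    stopifnot(inherits(aln, "alignment_set"))
    if (!is_count(window_bp) || window_bp < 1)
        stopf("window_bp must be a positive integer")
    window_bp <- as.integer(window_bp)
    sets <- names(aln$set_sizes)
    chroms <- names(aln$chrom_lengths)
    rows <- lapply(chroms, function(cn) {
        L <- aln$chrom_lengths[[cn]]
        n_win <- max(1L, as.integer(ceiling(L / window_bp)))
        starts <- (seq_len(n_win) - 1L) * window_bp
        ends <- pmin(starts + window_bp, L)
        h <- aln$hits[aln$hits$chrom == cn, , drop = FALSE]
        win <- pmin(h$start %/% window_bp, n_win - 1L)
        cnt <- table(factor(h$probe_set, sets), factor(win, 0:(n_win - 1L)))
        data.frame(chrom = cn,
                   start = rep(starts, each = length(sets)),
                   end = rep(ends, each = length(sets)),
                   probe_set = rep(sets, n_win),
                   count = as.integer(cnt),
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    density_profile(df$chrom, df$start, df$end, df$probe_set, df$count,
                    window_bp, aln$chrom_lengths)
}

#' Signal-call thresholds
#'
#' `candidate_min` is the display/candidate cutoff (a probe set with more
#' distinct oligos than this on a chromosome can in principle produce a
#' visible signal); `confident_min` bounds an "uncertain" band above it,
#' reflecting that counts between the two have been observed both to
#' produce and to fail to produce microscope signals.
#'
#' @param candidate_min candidate cutoff (default 1000 distinct oligos).
#' @param confident_min confident cutoff (default 3000).
#' @return A list of class `signal_thresholds`.
#' @export
signal_thresholds <- function(candidate_min = 1000L, confident_min = 3000L) {
    if (!is_count(candidate_min) || !is_count(confident_min))
        stopf("thresholds must be integers")
    if (candidate_min > confident_min)
        stopf("candidate_min (%d) must not exceed confident_min (%d)",
              candidate_min, confident_min)
    structure(list(candidate_min = as.integer(candidate_min),
                   confident_min = as.integer(confident_min)),
              class = "signal_thresholds")
}

#' Call predicted FISH signal levels from a count matrix
#'
#' Levels per (probe set, chromosome): `none` below `candidate_min`,
#' `uncertain` in `[candidate_min, confident_min)`, `present` at or above
#' `confident_min`.  When a density profile from the same alignment set is
#' supplied, cells at candidate level or above also get a signal pattern:
#' their window-count vector normalized to sum 1.
#'
#' @param matrix a `count_matrix`.
#' @param thresholds [signal_thresholds()].
#' @param profile optional [density_profile()] with identical probe-set
#'   and chromosome labels.
#' @return An object of class `signal_call`: list with `counts`, `levels`
#'   (character matrices), `patterns` (nested list
#'   `patterns[[probe_set]][[chrom]]`), `thresholds`, `window_bp`.
#' @export
call_signals <- function(matrix, thresholds = signal_thresholds(),
                         profile = NULL) {
    stopifnot(inherits(matrix, "count_matrix"),
              inherits(thresholds, "signal_thresholds"))
    lev <- ifelse(matrix >= thresholds$confident_min, "present",
                  ifelse(matrix >= thresholds$candidate_min, "uncertain",
                         "none"))
    dimnames(lev) <- dimnames(matrix)
    patterns <- list()
    window_bp <- NULL
    if (!is.null(profile)) {
        stopifnot(inherits(profile, "density_profile"))
        if (!setequal(unique(profile$probe_set), rownames(matrix)) ||
            !setequal(unique(profile$chrom), colnames(matrix)))
            stopf("density profile labels do not match the count matrix")
        window_bp <- attr(profile, "window_bp")
        for (ps in rownames(matrix)) {
            for (cn in colnames(matrix)) {
                if (matrix[ps, cn] < thresholds$candidate_min) next
                sel <- profile$probe_set == ps & profile$chrom == cn
                w <- profile[sel, , drop = FALSE]
                w <- w[order(w$start), , drop = FALSE]
                tot <- sum(w$count)
                if (tot > 0)
                    patterns[[ps]][[cn]] <- w$count / tot
            }
        }
    }
    structure(list(counts = matrix, levels = lev, patterns = patterns,
                   thresholds = thresholds, window_bp = window_bp),
              class = "signal_call")
}

#' @export
print.signal_call <- function(x, ...) {
    cat(sprintf(
        "signal calls: %d probe sets x %d chromosomes (candidate >= %d, confident >= %d)\n",
        nrow(x$levels), ncol(x$levels), x$thresholds$candidate_min,
        x$thresholds$confident_min))
    abbrev <- matrix(c(none = ".", uncertain = "?", present = "*")[x$levels],
                     nrow(x$levels), dimnames = dimnames(x$levels))
    print(as.data.frame(abbrev))
    invisible(x)
}

#' Candidate chromosome set of one probe
#'
#' @param calls a `signal_call`.
#' @param probe_set probe-set label.
#' @param min_level minimum level that counts as a candidate.
#' @return Character vector of chromosome labels.
#' @export
candidate_chromosomes <- function(calls, probe_set,
                                  min_level = c("uncertain", "present")) {
    stopifnot(inherits(calls, "signal_call"))
    min_level <- match.arg(min_level)
    if (!probe_set %in% rownames(calls$levels))
        stopf("unknown probe set: %s", probe_set)
    lv <- calls$levels[probe_set, ]
    keep <- if (min_level == "present") lv == "present" else lv != "none"
    colnames(calls$levels)[keep]
}

# binary barcode matrix (chromosomes x probes) at a level cutoff;
# extra_probes is a named chr vector probe -> chromosome lit
barcode_matrix <- function(calls, probes, min_level = "uncertain",
                           extra_probes = NULL) {
    chroms <- colnames(calls$levels)
    B <- matrix(0L, length(chroms), length(probes),
                dimnames = list(chroms, probes))
    for (p in probes) {
        if (p %in% rownames(calls$levels)) {
            lv <- calls$levels[p, ]
            B[, p] <- as.integer(
                if (min_level == "present") lv == "present" else lv != "none")
        } else if (!is.null(extra_probes) && p %in% names(extra_probes)) {
            B[, p] <- as.integer(chroms == extra_probes[[p]])
        } else {
            stopf("probe '%s' is neither in the signal calls nor an extra probe", p)
        }
    }
    B
}

#' Binary chromosome barcodes over a probe subset
#'
#' Each chromosome's barcode is the presence/absence vector (signal level
#' at or above `min_level`) over the chosen probes.  The collision report
#' lists chromosome groups sharing a barcode; the all-zero barcode group
#' is always listed because a dark chromosome cannot be positively
#' identified regardless of uniqueness.
#'
#' @param calls a `signal_call`.
#' @param probe_subset character vector of probe-set labels (default all).
#' @param min_level `"uncertain"` (candidate and above) or `"present"`.
#' @return An object of class `barcode_set`: list with `barcodes`
#'   (0/1 matrix, chromosomes x probes), `collisions` (list of chromosome
#'   groups with >= 2 members sharing a barcode), `zero_group`
#'   (chromosomes with the all-zero barcode).
#' @export
barcode_chromosomes <- function(calls, probe_subset = NULL,
                                min_level = c("uncertain", "present")) {
    stopifnot(inherits(calls, "signal_call"))
    min_level <- match.arg(min_level)
    if (is.null(probe_subset)) probe_subset <- rownames(calls$levels)
    unknown <- setdiff(probe_subset, rownames(calls$levels))
    if (length(unknown))
        stopf("probe subset contains unknown probe set: %s", unknown[1])
    B <- if (length(probe_subset) == 0) {
        matrix(0L, ncol(calls$levels), 0,
               dimnames = list(colnames(calls$levels), NULL))
    } else {
        barcode_matrix(calls, probe_subset, min_level)
    }
    key <- if (ncol(B) == 0) rep("", nrow(B)) else
        apply(B, 1, paste, collapse = "")
    groups <- split(rownames(B), key)
    zero_key <- paste(rep("0", ncol(B)), collapse = "")
    collisions <- groups[vapply(groups, length, integer(1)) >= 2 |
                         names(groups) == zero_key]
    collisions <- unname(collisions[order(names(collisions))])
    zero_idx <- which(names(groups) == zero_key)
    structure(list(barcodes = B,
                   collisions = collisions,
                   zero_group = if (length(zero_idx))
                       groups[[zero_idx]] else character(0)),
              class = "barcode_set")
}

#' @export
print.barcode_set <- function(x, ...) {
    cat(sprintf("chromosome barcodes over %d probe(s)\n", ncol(x$barcodes)))
    print(x$barcodes)
    if (length(x$collisions)) {
        cat("colliding groups:\n")
        for (g in x$collisions)
            cat("  {", paste(g, collapse = ", "), "}\n")
    } else cat("all barcodes distinct and non-zero\n")
    invisible(x)
}
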