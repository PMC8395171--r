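# Shared fixtures built in code.

# Synthetic along-chromosome density profile consistent with the packaged
# published count matrix (the source figures are not tabulated, so window
# shapes here are synthetic): uniform whole-chromosome coverage by default,
# distal concentration for selected (probe set, chromosome) cells.
published_profile <- function(m, n_win = 20L, chrom_len = 10e6,
                              distal = list(c("MCP3", "Sorghum8"),
                                            c("MCP10", "Sorghum8"))) {
    win <- as.integer(chrom_len / n_win)
    rows <- list()
    distal_keys <- vapply(distal, paste, character(1), collapse = "|")
    for (ps in rownames(m)) {
        for (cn in colnames(m)) {
            cnt <- m[ps, cn]
            shape <- if (paste(ps, cn, sep = "|") %in% distal_keys)
                "distal" else "uniform"
            counts <- integer(n_win)
            if (shape == "uniform") {
                counts[] <- cnt %/% n_win
                r <- cnt %% n_win
                if (r > 0) counts[seq_len(r)] <- counts[seq_len(r)] + 1L
            } else {
                tail_idx <- (n_win - 3L):n_win
                counts[tail_idx] <- cnt %/% 4L
                r <- cnt %% 4L
                if (r > 0)
                    counts[tail_idx[seq_len(r)]] <-
                        counts[tail_idx[seq_len(r)]] + 1L
            }
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = cn, start = (seq_len(n_win) - 1L) * win,
                end = seq_len(n_win) * win, probe_set = ps,
                count = counts, stringsAsFactors = FALSE)
        }
    }
    df <- do.call(rbind, rows)
    density_profile(df$chrom, df$start, df$end, df$probe_set, df$count,
                    win)
}

published_calls <- function(with_patterns = FALSE, ...) {
    m <- sorghum_mcp_counts()
    if (with_patterns)
        call_signals(m, signal_thresholds(), published_profile(m, ...))
    else call_signals(m, signal_thresholds())
}

# signal_call from explicit candidate sets: probe -> chromosomes lit
toy_calls <- function(candidate_sets, chroms,
                      lit_count = 2000L, thresholds = signal_thresholds()) {
    m <- matrix(0L, length(candidate_sets), length(chroms),
                dimnames = list(if (length(candidate_sets))
                    names(candidate_sets) else character(0), chroms))
    for (p in names(candidate_sets))
        m[p, candidate_sets[[p]]] <- lit_count
    call_signals(count_matrix(m), thresholds)
}

# hand-built alignment_set (bypasses screening) for profile-level tests
manual_alignment_set <- function(hits, chrom_lengths, set_sizes,
                                 params = screen_params()) {
    structure(list(hits = hits, params = params,
                   chrom_lengths = chrom_lengths, set_sizes = set_sizes,
                   retained_per_set = setNames(
                       vapply(names(set_sizes), function(s)
                           length(unique(hits$oligo_id[hits$probe_set == s])),
                           integer(1)), names(set_sizes)),
                   library_id = "manual", genome_id = "manual"),
              class = "alignment_set")
}

# single-cell measurement table built from published per-chromosome arm
# means (one homolog copy per chromosome)
published_single_cell <- function() {
    kt <- tripidium_karyotype()
    data.frame(cell_id = "cell01", chrom_label = kt$chrom_label,
               long_arm_um = kt$long_mean, short_arm_um = kt$short_mean,
               stringsAsFactors = FALSE)
}
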