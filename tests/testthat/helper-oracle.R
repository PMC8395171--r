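# Brute-force ungapped screening oracle, independent of the package's C++
# search path: scores every full-length placement on both strands with
# vectorized base R and applies the retention rule directly.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(L) paste(sample(BASES, L, replace = TRUE), collapse = "")

rand_genome <- function(n_chrom, L) {
    setNames(vapply(seq_len(n_chrom), function(i) rand_seq(L), character(1)),
             paste0("g", seq_len(n_chrom)))
}

enc_int <- function(s, sentinel) {
    v <- match(strsplit(s, "", fixed = TRUE)[[1]], BASES)
    v[is.na(v)] <- sentinel
    v
}

revcomp_int <- function(v) {
    r <- rev(v)
    ifelse(r %in% 1:4, 5L - r, r)
}

# genome: named character vector
oracle_screen <- function(lib, genome, min_match = 32, frac = 0.70) {
    rows <- list()
    for (cn in names(genome)) {
        gv <- enc_int(genome[[cn]], sentinel = -2L)
        L <- length(gv)
        for (i in seq_len(nrow(lib))) {
            m <- lib$length[i]
            if (L < m) next
            thr <- max(min_match, ceiling(frac * m - 1e-9))
            n_off <- L - m + 1L
            fwd <- enc_int(lib$sequence[i], sentinel = -1L)
            for (strand in c("+", "-")) {
                ov <- if (strand == "+") fwd else revcomp_int(fwd)
                cnt <- integer(n_off)
                for (j in seq_len(m))
                    cnt <- cnt + (gv[j:(j + n_off - 1L)] == ov[j])
                w <- which(cnt >= thr)
                if (length(w))
                    rows[[length(rows) + 1L]] <- data.frame(
                        oligo_id = lib$oligo_id[i], chrom = cn,
                        start = w - 1L, strand = strand,
                        matched_bases = cnt[w], stringsAsFactors = FALSE)
            }
        }
    }
    if (length(rows) == 0)
        return(data.frame(oligo_id = character(), chrom = character(),
                          start = integer(), strand = character(),
                          matched_bases = integer(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    out[order(out$oligo_id, out$chrom, out$start, out$strand), ]
}

hit_key <- function(df) {
    sort(sprintf("%s|%s|%d|%s|%d", df$oligo_id, df$chrom, df$start,
                 df$strand, df$matched_bases))
}

# mutate `n_mut` positions of a sequence (always to a different base)
mutate_seq <- function(s, positions) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in positions) {
        v[p] <- sample(setdiff(BASES, v[p]), 1)
    }
    paste(v, collapse = "")
}
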