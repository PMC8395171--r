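mini_aln <- function(hits_df, chrom_lengths, set_sizes) {
    manual_alignment_set(hits_df, chrom_lengths, set_sizes)
}

test_that("counting deduplicates oligos per chromosome but not across them", {
    hits <- data.frame(
        oligo_id = c("A_1", "A_1", "A_2", "A_2", "A_3", "A_3"),
        probe_set = "A",
        chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1"),
        start = c(0L, 100L, 200L, 300L, 400L, 500L),
        end = c(45L, 145L, 245L, 345L, 445L, 545L),
        strand = "+", matched_bases = 45L, span_bp = 45L, identity = 1,
        stringsAsFactors = FALSE)
    aln <- mini_aln(hits, c(chr1 = 1000L, chr2 = 800L), c(A = 3L))
    m <- count_per_chromosome(aln)
    expect_identical(m["A", "chr1"], 3L)
    # chromosome without hits is preserved with a zero column
    expect_identical(m["A", "chr2"], 0L)

    empty <- mini_aln(hits[0, ], c(chr1 = 1000L), c(A = 3L))
    expect_true(all(count_per_chromosome(empty) == 0L))
})

test_that("a multi-chromosome oligo adds one to each chromosome it hits", {
    # homoeologous-complement situation: one oligo on three chromosomes
    hits <- data.frame(
        oligo_id = rep(c("H_1", "H_2"), each = 3),
        probe_set = "H",
        chrom = rep(c("c1", "c2", "c3"), 2),
        start = 0L, end = 45L, strand = "+", matched_bases = 45L,
        span_bp = 45L, identity = 1, stringsAsFactors = FALSE)
    aln <- mini_aln(hits, c(c1 = 100L, c2 = 100L, c3 = 100L), c(H = 2L))
    m <- count_per_chromosome(aln)
    expect_identical(unname(m["H", ]), c(2L, 2L, 2L))
    # row sum exceeds the probe-set size, as a per-oligo tally confirms
    tally <- table(unique(hits[, c("oligo_id", "chrom")])$chrom)
    expect_identical(unname(rowSums(m)), 6)
    expect_identical(as.integer(tally), c(2L, 2L, 2L))
})

test_that("matrix extrema report values with their labels and ties", {
    m <- count_matrix(matrix(c(1L, 3L, 2L, 4L), 2, 2,
                             dimnames = list(c("A", "B"), c("x", "y"))))
    ext <- matrix_extrema(m)
    expect_identical(ext$min_value, 1L)
    expect_identical(ext$max_value, 4L)
    expect_identical(ext$min_cells$probe_set, "A")
    expect_identical(ext$max_cells$chrom, "y")

    flat <- count_matrix(matrix(5L, 2, 2,
                                dimnames = list(c("A", "B"), c("x", "y"))))
    ef <- matrix_extrema(flat)
    expect_identical(ef$min_value, ef$max_value)
    expect_identical(nrow(ef$min_cells), 4L)
})

test_that("window assignment is half-open on the start coordinate", {
    hits <- data.frame(
        oligo_id = c("A_1", "A_2", "A_3"), probe_set = "A",
        chrom = "chr1", start = c(499999L, 500000L, 1100000L),
        end = c(500044L, 500045L, 1100045L), strand = "+",
        matched_bases = 45L, span_bp = 45L, identity = 1,
        stringsAsFactors = FALSE)
    aln <- mini_aln(hits, c(chr1 = 1200000L), c(A = 3L))
    prof <- bin_density(aln, 500000L)
    expect_identical(nrow(prof), 3L)
    expect_identical(prof$end, c(500000L, 1000000L, 1200000L))
    expect_identical(prof$count, c(1L, 1L, 1L))
})

test_that("window counts conserve the per-chromosome totals", {
    set.seed(31)
    g <- c(c1 = rand_seq(40000), c2 = rand_seq(25000))
    starts <- sample(1:35000, 50)
    lib <- oligo_library(sprintf("A_%03d", 1:50), "A",
                         substring(g[["c1"]], starts, starts + 44))
    aln <- screen_library(lib, g)
    m <- count_per_chromosome(aln)
    prof <- bin_density(aln, 5000L)
    for (cn in names(g)) {
        wsum <- sum(prof$count[prof$chrom == cn & prof$probe_set == "A"])
        expect_gte(wsum, m["A", cn])
        expect_identical(
            m["A", cn],
            length(unique(aln$hits$oligo_id[aln$hits$chrom == cn])))
    }
    # every chromosome is present in the profile even without hits
    expect_setequal(unique(prof$chrom), names(g))
})

test_that("uniform hits fill windows uniformly (chi-square, 20 replicates)", {
    set.seed(32)
    rejections <- 0L
    for (rep in 1:20) {
        n <- 400L
        starts <- sample(0:(1000000L - 45L), n, replace = TRUE)
        hits <- data.frame(oligo_id = sprintf("U_%04d", seq_len(n)),
                           probe_set = "U", chrom = "c1", start = starts,
                           end = starts + 45L, strand = "+",
                           matched_bases = 45L, span_bp = 45L, identity = 1,
                           stringsAsFactors = FALSE)
        aln <- mini_aln(hits, c(c1 = 1000000L), c(U = n))
        prof <- bin_density(aln, 100000L)
        pval <- suppressWarnings(
            stats::chisq.test(prof$count)$p.value)
        if (pval < 0.01) rejections <- rejections + 1L
    }
    # nominal 1% level: allow at most one rejection across 20 replicates
    expect_lte(rejections, 1L)
})

test_that("signal levels follow the two-tier thresholds", {
    m <- sorghum_mcp_counts()
    calls <- call_signals(m)
    expect_setequal(candidate_chromosomes(calls, "MCP1"),
                    c("Sorghum1", "Sorghum7", "Sorghum8"))
    expect_setequal(candidate_chromosomes(calls, "MCP10"),
                    c("Sorghum6", "Sorghum7", "Sorghum8", "Sorghum9"))
    expect_identical(calls$levels["MCP10", "Sorghum9"], "uncertain")
    expect_identical(calls$levels["MCP1", "Sorghum1"], "present")
    expect_identical(calls$levels["MCP9", "Sorghum5"], "none")

    zero <- count_matrix(matrix(0L, 2, 2,
                                dimnames = list(c("A", "B"), c("x", "y"))))
    expect_true(all(call_signals(zero)$levels == "none"))
})

test_that("raising the candidate threshold never grows a candidate set", {
    m <- sorghum_mcp_counts()
    lo <- call_signals(m, signal_thresholds(500L, 3000L))
    hi <- call_signals(m, signal_thresholds(2000L, 3000L))
    for (p in rownames(m)) {
        expect_true(all(candidate_chromosomes(hi, p) %in%
                        candidate_chromosomes(lo, p)))
    }
    expect_error(signal_thresholds(3000L, 1000L), "must not exceed")
})

test_that("patterns require label-consistent profiles and normalize to one", {
    m <- sorghum_mcp_counts()
    prof <- published_profile(m)
    calls <- call_signals(m, signal_thresholds(), prof)
    p <- calls$patterns[["MCP1"]][["Sorghum1"]]
    expect_equal(sum(p), 1)
    # below-candidate cells carry no pattern
    expect_null(calls$patterns[["MCP9"]][["Sorghum5"]])

    bad <- prof
    bad$chrom[bad$chrom == "Sorghum1"] <- "SorghumX"
    class(bad) <- class(prof)
    expect_error(call_signals(m, signal_thresholds(), bad),
                 "labels do not match")
})

test_that("barcodes over MCP5-10 leave two published collisions", {
    calls <- published_calls()
    bc <- barcode_chromosomes(calls, paste0("MCP", 5:10))
    expect_identical(bc$zero_group, "Sorghum5")
    groups <- lapply(bc$collisions, sort)
    expect_true(list(c("Sorghum6", "Sorghum8")) %in% groups ||
                any(vapply(groups, identical, logical(1),
                           c("Sorghum6", "Sorghum8"))))
    # the full probe panel separates all ten chromosomes
    bc_all <- barcode_chromosomes(calls)
    expect_identical(length(bc_all$collisions), 0L)
    expect_identical(nrow(unique(bc_all$barcodes)), 10L)
})

test_that("an empty probe subset collides every chromosome", {
    calls <- published_calls()
    bc <- barcode_chromosomes(calls, character(0))
    expect_identical(sort(bc$zero_group), sort(colnames(calls$levels)))
    expect_identical(length(bc$collisions), 1L)
})
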