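test_that("reference genomes are reproducible with near-uniform composition", {
    cfg <- sim_config(seed = 3, n_chrom = 2L,
                      chrom_lengths_bp = c(1000000L, 1000000L))
    g1 <- simulate_reference_genome(cfg)$genome
    g2 <- simulate_reference_genome(cfg)$genome
    expect_identical(as.character(g1), as.character(g2))
    expect_identical(unname(Biostrings::width(g1)), c(1000000L, 1000000L))
    gc <- Biostrings::letterFrequency(g1, "GC", as.prob = TRUE)
    expect_true(all(gc > 0.49 & gc < 0.51))
    # a different seed changes the sequence
    g3 <- simulate_reference_genome(sim_config(seed = 4, n_chrom = 2L,
        chrom_lengths_bp = c(1000000L, 1000000L)))$genome
    expect_false(identical(as.character(g1), as.character(g3)))
})

test_that("library design hits the target density with single-copy oligos", {
    cfg <- sim_config(seed = 5, n_chrom = 1L, chrom_lengths_bp = 1000000L)
    ref <- simulate_reference_genome(cfg)
    des <- design_oligo_library(ref$genome, cfg)
    expect_identical(nrow(des$library), 250L)  # 1 Mb at 0.25 per kb
    expect_identical(unique(des$library$probe_set), "CP1")
    expect_identical(nrow(des$truth), nrow(des$library))

    # exhaustive single-copy check on a small genome
    cfg2 <- sim_config(seed = 6, n_chrom = 2L,
                       chrom_lengths_bp = c(20000L, 15000L),
                       oligo_density_per_kb = 2)
    ref2 <- simulate_reference_genome(cfg2)
    des2 <- design_oligo_library(ref2$genome, cfg2)
    for (i in seq_len(nrow(des2$library))) {
        s <- des2$library$sequence[i]
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
        n_occ <- sum(vapply(as.character(ref2$genome), function(chr) {
            length(gregexpr(s, chr, fixed = TRUE)[[1]][
                gregexpr(s, chr, fixed = TRUE)[[1]] > 0]) +
            length(gregexpr(rc, chr, fixed = TRUE)[[1]][
                gregexpr(rc, chr, fixed = TRUE)[[1]] > 0])
        }, numeric(1)))
        expect_identical(n_occ, 1)
    }
})

test_that("a library screens perfectly against its own source genome", {
    cfg <- sim_config(seed = 7, n_chrom = 2L,
                      chrom_lengths_bp = c(50000L, 40000L),
                      oligo_density_per_kb = 1)
    ref <- simulate_reference_genome(cfg)
    des <- design_oligo_library(ref$genome, cfg)
    aln <- screen_library(des$library, ref$genome)
    expect_identical(sum(aln$retained_per_set), nrow(des$library))
    best <- tapply(aln$hits$identity, aln$hits$oligo_id, max)
    expect_true(all(best == 1))
    # truth log: the perfect hit lies at the recorded source locus
    perfect <- aln$hits[aln$hits$identity == 1 & aln$hits$strand == "+", ]
    key <- paste(perfect$oligo_id, perfect$chrom, perfect$start)
    truth_key <- paste(des$truth$oligo_id, des$truth$chrom, des$truth$start)
    expect_true(all(truth_key %in% key))
})

test_that("divergence is rate-faithful and nested across rates", {
    cfg <- sim_config(seed = 8, n_chrom = 1L, chrom_lengths_bp = 200000L)
    ref <- simulate_reference_genome(cfg)

    same <- diverge_genome(ref$genome, divergence_scenario("zero", 0),
                           seed = 8)
    expect_identical(as.character(same$genome), as.character(ref$genome))

    d10 <- diverge_genome(ref$genome, divergence_scenario("mid", 0.10),
                          seed = 8)
    frac <- d10$truth$n_substitutions / 200000
    expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / 200000))

    # common random numbers: lower-rate substitution sites are nested
    d05 <- diverge_genome(ref$genome, divergence_scenario("low", 0.05),
                          seed = 8)
    v0 <- strsplit(as.character(ref$genome[[1]]), "")[[1]]
    v05 <- strsplit(as.character(d05$genome[[1]]), "")[[1]]
    v10 <- strsplit(as.character(d10$genome[[1]]), "")[[1]]
    expect_true(all(which(v05 != v0) %in% which(v10 != v0)))
})

test_that("diverged oligos keep the expected matched-base count", {
    cfg <- sim_config(seed = 9, n_chrom = 1L, chrom_lengths_bp = 100000L,
                      oligo_density_per_kb = 2)
    ref <- simulate_reference_genome(cfg)
    des <- design_oligo_library(ref$genome, cfg)
    div <- diverge_genome(ref$genome, divergence_scenario("mid", 0.10),
                          seed = 9)
    aln <- screen_library(des$library, div$genome,
                          screen_params(mode = "exhaustive"))
    best <- tapply(aln$hits$matched_bases, aln$hits$oligo_id, max)
    n <- length(best)
    se <- sqrt(45 * 0.9 * 0.1) / sqrt(n)
    expect_lt(abs(mean(best) - 40.5), 3 * se + 0.2)
})

test_that("translocations move tagged segments and their rDNA sites", {
    cfg <- sim_config(seed = 10, n_chrom = 10L,
                      chrom_lengths_bp = rep(20000L, 10))
    ref <- simulate_reference_genome(cfg)
    rdna <- ref$truth$rdna_sites
    expect_identical(rdna$chrom, c("refChr9", "refChr6"))
    r5 <- rdna[rdna$name == "5S", ]
    div <- diverge_genome(
        ref$genome, divergence_scenario("zero", 0),
        list(translocation("refChr9", r5$start, r5$end, "refChr5", 1000L)),
        seed = 10, rdna_sites = rdna)
    moved <- div$truth$rdna_sites
    expect_identical(moved$chrom[moved$name == "5S"], "refChr5")
    seg_len <- r5$end - r5$start
    expect_identical(nchar(as.character(div$genome[["refChr9"]])),
                     20000L - seg_len)
    expect_identical(nchar(as.character(div$genome[["refChr5"]])),
                     20000L + seg_len)
    # the moved segment sits verbatim at its destination
    seg <- substring(as.character(ref$genome[["refChr9"]]),
                     r5$start + 1, r5$end)
    dest <- substring(as.character(div$genome[["refChr5"]]),
                      1001, 1000 + seg_len)
    expect_identical(dest, seg)

    expect_error(diverge_genome(
        ref$genome, divergence_scenario("zero", 0),
        list(translocation("refChr9", 100L, 300L, "refChr5", 0L),
             translocation("refChr9", 200L, 400L, "refChr4", 0L)),
        seed = 1), "overlapping")
})

test_that("polyploidization yields the full complement in source groups", {
    cfg <- sim_config(seed = 11, n_chrom = 10L,
                      chrom_lengths_bp = rep(5000L, 10))
    ref <- simulate_reference_genome(cfg)
    poly <- polyploidize(ref$genome, ploidy(60L, 10L), 0.005, seed = 11)
    expect_identical(length(poly$complement), 60L)
    expect_identical(nrow(poly$truth), 60L)
    expect_identical(as.integer(table(poly$truth$group)), rep(6L, 10))

    clean <- polyploidize(ref$genome, ploidy(60L, 10L), 0, seed = 11)
    for (i in c(1L, 10L)) {
        copies <- clean$truth$copy[clean$truth$group == i]
        seqs <- unique(as.character(clean$complement[copies]))
        expect_length(seqs, 1)
        expect_identical(seqs, as.character(ref$genome[[i]]))
    }
    expect_error(polyploidize(ref$genome, ploidy(60L, 12L), 0, 1),
                 "x_basic")
})

test_that("noise-free measurements reproduce the truth exactly", {
    arms <- default_true_arms(5)
    mm <- simulate_measurements(arms, 0, 4, ploidy(30L, 5L), 0, seed = 12)
    expect_identical(nrow(mm), 4L * 5L * 6L)  # cells x chromosomes x copies
    kt <- summarize_karyotype(mm)
    ord <- match(kt$chrom_label, arms$chrom_label)
    expect_equal(kt$long_mean, arms$long_um[ord], tolerance = 1e-12)
    expect_equal(kt$short_mean, arms$short_um[ord], tolerance = 1e-12)
    expect_equal(kt$ratio_mean, (arms$long_um / arms$short_um)[ord],
                 tolerance = 1e-12)
})

test_that("missing copies thin the records without breaking summaries", {
    arms <- default_true_arms(5)
    mm <- simulate_measurements(arms, 0.1, 10, ploidy(30L, 5L), 0.1,
                                seed = 13)
    full <- simulate_measurements(arms, 0.1, 10, ploidy(30L, 5L), 0,
                                  seed = 13)
    expect_lt(nrow(mm), nrow(full))
    expect_identical(nrow(full), 10L * 5L * 6L)
    kt <- summarize_karyotype(mm)
    expect_identical(nrow(kt), 5L)
    expect_true(all(kt$n_cells <= 10))
})
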