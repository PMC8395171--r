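test_that("single-cell arithmetic reproduces the published totals and
           ratios", {
    kt <- summarize_karyotype(published_single_cell())
    get <- function(col, chrom) kt[[col]][kt$chrom_label == chrom]
    expect_equal(get("total_mean", "Chr.1"), 3.58)
    expect_equal(get("total_mean", "Chr.8"), 2.50)
    expect_equal(get("total_mean", "Chr.4"), 3.13)
    expect_equal(floor(get("ratio_mean", "Chr.10") * 100 + 0.5) / 100, 1.14)
    expect_equal(floor(get("ratio_mean", "Chr.2") * 100 + 0.5) / 100, 1.32)
    expect_equal(get("ratio_mean", "Chr.1"), 2.02 / 1.56, tolerance = 1e-12)
    # every published arm ratio is metacentric except Chr.6
    expect_identical(kt$centromere_class[kt$chrom_label == "Chr.6"], "sm")
    expect_true(all(kt$centromere_class[kt$chrom_label != "Chr.6"] == "m"))
    # totals equal long + short exactly before rounding
    expect_equal(kt$total_mean, kt$long_mean + kt$short_mean,
                 tolerance = 1e-12)
})

test_that("the arm ratio is the mean of per-cell ratios, not the ratio of
           means", {
    mm <- data.frame(cell_id = c("c1", "c2"), chrom_label = "chr1",
                     long_arm_um = c(2, 3), short_arm_um = c(1, 2))
    kt <- summarize_karyotype(mm)
    expect_equal(kt$ratio_mean, mean(c(2 / 1, 3 / 2)))      # 1.75
    expect_false(isTRUE(all.equal(kt$ratio_mean, 2.5 / 1.5)))
})

test_that("homolog copies are averaged within a cell before statistics", {
    mm <- data.frame(cell_id = "c1", chrom_label = "chr1",
                     long_arm_um = c(2, 4), short_arm_um = c(1, 3))
    kt <- summarize_karyotype(mm)
    expect_equal(kt$long_mean, 3)
    expect_equal(kt$short_mean, 2)
    expect_equal(kt$ratio_mean, 1.5)  # 3/2, not mean(2/1, 4/3)
    expect_identical(kt$n_cells, 1L)
})

test_that("summaries are invariant to row and cell permutations", {
    set.seed(51)
    arms <- default_true_arms(4)
    mm <- simulate_measurements(arms, 0.1, 6, ploidy(24L, 4L), 0, seed = 5)
    k1 <- summarize_karyotype(mm)
    k2 <- summarize_karyotype(mm[sample(nrow(mm)), ])
    expect_equal(as.data.frame(k1), as.data.frame(k2))
})

test_that("degenerate measurements are swapped or rejected", {
    swapped <- data.frame(cell_id = "c1", chrom_label = "chr1",
                          long_arm_um = 1.0, short_arm_um = 2.0)
    expect_warning(kt <- summarize_karyotype(swapped), "swapped")
    expect_equal(kt$long_mean, 2.0)
    expect_equal(kt$ratio_mean, 2.0)

    expect_error(summarize_karyotype(
        data.frame(cell_id = "c1", chrom_label = "chr1",
                   long_arm_um = 2, short_arm_um = 0)), "positive")
    expect_error(summarize_karyotype(
        data.frame(cell_id = "c1", chrom_label = "chrX",
                   long_arm_um = 2, short_arm_um = 1),
        chrom_labels = paste0("chr", 1:10)), "unknown chromosome")
})

test_that("centromere classes follow the conventional boundaries", {
    expect_identical(classify_centromere(c(1.0, 1.14, 1.7)),
                     c("m", "m", "m"))
    expect_identical(classify_centromere(c(1.71, 2.03, 3.0)),
                     c("sm", "sm", "sm"))
    expect_identical(classify_centromere(c(3.01, 7.0)), c("st", "st"))
    expect_identical(classify_centromere(7.01), "t")
    expect_error(classify_centromere(0.9), ">= 1")
    # monotone: classes never step back as the ratio grows
    ratios <- seq(1, 10, by = 0.1)
    cls <- match(classify_centromere(ratios), c("m", "sm", "st", "t"))
    expect_true(all(diff(cls) >= 0))
})

test_that("reference numbering transfers by exact barcode identity", {
    sets <- list(p1 = "r1", p2 = "r2", p3 = c("r1", "r3"))
    ref <- toy_calls(sets, c("r1", "r2", "r3"))
    tgt <- toy_calls(list(p1 = "t1", p2 = "t2", p3 = c("t1", "t3")),
                     c("t1", "t2", "t3", "t4"))
    map <- assign_reference_numbers(tgt, ref)
    expect_identical(map$assigned_ref[map$target == "t1"], "r1")
    expect_identical(map$assigned_ref[map$target == "t2"], "r2")
    expect_identical(map$assigned_ref[map$target == "t3"], "r3")
    expect_identical(map$status[map$target == "t4"], "unassigned")

    # ambiguous when two references share the matching barcode
    ref2 <- toy_calls(list(p1 = c("r1", "r2")), c("r1", "r2"))
    tgt2 <- toy_calls(list(p1 = "t1"), "t1")
    expect_identical(assign_reference_numbers(tgt2, ref2)$status,
                     "ambiguous")
})

test_that("a hexaploid complement recovers its source numbering", {
    cfg <- sim_config(seed = 77, n_chrom = 4L,
                      chrom_lengths_bp = rep(12000L, 4),
                      oligo_density_per_kb = 2,
                      ploidy = ploidy(24L, 4L))
    ref <- simulate_reference_genome(cfg)
    lib <- design_oligo_library(ref$genome, cfg)$library
    div <- diverge_genome(ref$genome, divergence_scenario("near", 0.03),
                          NULL, seed = 77)
    poly <- polyploidize(div$genome, ploidy(24L, 4L), 0.003, seed = 77)
    p <- screen_params(seed_k = 12L)
    thr <- signal_thresholds(10L, 15L)
    ref_calls <- call_signals(
        count_per_chromosome(screen_library(lib, ref$genome, p)), thr)
    tgt_calls <- call_signals(
        count_per_chromosome(screen_library(lib, poly$complement, p)), thr)
    # every probe set's candidate set includes its own source group
    for (i in 1:4) {
        cand <- candidate_chromosomes(tgt_calls, sprintf("CP%d", i))
        grp <- poly$truth$copy[poly$truth$group == i]
        expect_true(all(grp %in% cand))
    }
    map <- assign_reference_numbers(tgt_calls, ref_calls)
    expect_true(all(map$status == "matched"))
    truth_src <- poly$truth$source_chrom[match(map$target,
                                               poly$truth$copy)]
    expect_identical(map$assigned_ref, truth_src)
})

test_that("idiograms order and scale bars and place annotations", {
    kt <- summarize_karyotype(published_single_cell())
    expect_identical(kt$chrom_label[which.max(kt$total_mean)], "Chr.1")
    expect_identical(kt$chrom_label[which.min(kt$total_mean)], "Chr.8")
    ann <- data.frame(
        chrom = c("Chr.5", "Chr.6"), label = c("5S", "35S"),
        color = c("#d62728", "#2ca02c"),
        region = c("pericentromeric", "distal-long"),
        stringsAsFactors = FALSE)
    idi <- build_idiogram(kt, ann)
    svg1 <- tempfile(fileext = ".svg"); svg2 <- tempfile(fileext = ".svg")
    write_idiogram_svg(idi, svg1)
    write_idiogram_svg(idi, svg2)
    expect_identical(readLines(svg1), readLines(svg2))
    txt <- readLines(svg1)
    expect_true(any(grepl("#d62728", txt)))
    expect_true(any(grepl("#2ca02c", txt)))
    expect_identical(sum(grepl("<text.*Chr\\.", txt)), 10L)

    expect_error(build_idiogram(kt, data.frame(
        chrom = "Chr.99", label = "x", color = "red", region = "whole")),
        "missing chromosome")
    expect_error(build_idiogram(kt, data.frame(
        chrom = "Chr.1", label = "x", color = "red", region = "middle")),
        "unknown annotation region")

    js <- tempfile(fileext = ".json")
    write_idiogram_json(idi, js)
    parsed <- jsonlite::read_json(js)
    expect_length(parsed$chromosomes, 10)
})

test_that("single-bar idiograms render with a centromere mark", {
    mm <- data.frame(cell_id = "c1", chrom_label = "chr1",
                     long_arm_um = 1.0, short_arm_um = 1.0)
    kt <- summarize_karyotype(mm)
    expect_equal(kt$ratio_mean, 1.0)
    expect_identical(kt$centromere_class, "m")
    svg <- tempfile(fileext = ".svg")
    write_idiogram_svg(build_idiogram(kt), svg)
    txt <- readLines(svg)
    expect_identical(sum(grepl("<line", txt)), 1L)
    expect_identical(sum(grepl('<rect x=', txt, fixed = TRUE)), 1L)
})
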