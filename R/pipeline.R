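#' Demonstration pipeline configuration
#'
#' A fully seeded desk-scale preset: a 10-chromosome reference (60-150 kb
#' chromosomes), a 45-nt painting library at 0.25 oligo per kb, a target
#' genome diverged at 0.10 substitutions per site carrying a 5S-analog
#' translocation (ninth to fifth chromosome), rDNA extra probes, and 10
#' noisy metaphase cells for the karyotype stage.  Signal thresholds are
#' scaled to the desk-scale library (candidate 8, confident 12 distinct
#' oligos).
#'
#' @param seed master seed.
#' @param out_dir output directory for stage artifacts.
#' @return A list of class `pipeline_config`.
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("oligofish_run_")) {
    n_chrom <- 10L
    lengths <- as.integer(round(seq(150e3, 60e3, length.out = n_chrom)))
    sim <- sim_config(seed = seed, n_chrom = n_chrom,
                      chrom_lengths_bp = lengths,
                      scenario = divergence_scenario("reference-target",
                                                     0.10, 11.9))
    structure(list(
        seed = as.integer(seed),
        out_dir = out_dir,
        sim = sim,
        library_path = NULL, genome_path = NULL, measurements_path = NULL,
        screen = screen_params(seed_k = 12L, mode = "seed"),
        window_bp = 10000L,
        thresholds = signal_thresholds(candidate_min = 8L,
                                       confident_min = 12L),
        constraints = plan_constraints(
            extra_probes = c("5S" = "refChr5", "35S" = "refChr6")),
        true_arms = default_true_arms(n_chrom),
        write_files = TRUE), class = "pipeline_config")
}

with_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stopf("stage '%s': %s", name, conditionMessage(e)))
}

#' Run the full painting-analysis pipeline
#'
#' Executes simulate (when a simulation config is present) -> screen ->
#' profile (counts, density, signal calls, barcodes) -> plan ->
#' karyotype, writing stage artifacts and a machine-readable JSON run
#' report.  Deterministic: identical configuration produces identical
#' artifacts and report.  Any stage error aborts with the stage name;
#' artifacts of completed stages are preserved.
#'
#' @param config a [demo_config()]-style `pipeline_config` list.
#' @return The run report (list), invisibly written to
#'   `<out_dir>/report.json`.
#' @export
run_pipeline <- function(config) {
    stopifnot(inherits(config, "pipeline_config"))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    stages <- list()
    lib <- NULL; target <- NULL; meas <- NULL
    rdna <- NULL

    if (!is.null(config$sim)) {
        sim_res <- with_stage("simulate", {
            ref <- simulate_reference_genome(config$sim)
            des <- design_oligo_library(ref$genome, config$sim)
            rear <- NULL
            if (!is.null(ref$truth$rdna_sites)) {
                r5 <- ref$truth$rdna_sites[
                    ref$truth$rdna_sites$name == "5S", ]
                dest <- "refChr5"
                if (nrow(r5) == 1 && dest %in% names(ref$genome) &&
                    r5$chrom != dest)
                    rear <- list(translocation(
                        r5$chrom, r5$start, r5$end, dest,
                        as.integer(0.5 * config$sim$chrom_lengths_bp[5])))
            }
            div <- diverge_genome(ref$genome, config$sim$scenario, rear,
                                  seed = config$sim$seed,
                                  rdna_sites = ref$truth$rdna_sites)
            mm <- simulate_measurements(
                config$true_arms, config$sim$measurement_noise_sd_um,
                config$sim$n_cells, config$sim$ploidy, 0,
                seed = config$sim$seed)
            if (config$write_files) {
                write_genome(ref$genome,
                             file.path(config$out_dir, "reference.fa"))
                write_genome(div$genome,
                             file.path(config$out_dir, "target.fa"))
                write_oligo_library(des$library,
                                    file.path(config$out_dir, "library.fa"))
                write_measurements(mm, file.path(config$out_dir,
                                                 "measurements.tsv"))
                jsonlite::write_json(
                    list(oligo_truth = des$truth,
                         divergence = div$truth$n_substitutions,
                         rdna_sites = div$truth$rdna_sites),
                    file.path(config$out_dir, "truth.json"),
                    auto_unbox = TRUE, digits = NA, pretty = TRUE)
            }
            list(lib = des$library, target = div$genome, meas = mm,
                 rdna = div$truth$rdna_sites)
        })
        lib <- sim_res$lib; target <- sim_res$target
        meas <- sim_res$meas; rdna <- sim_res$rdna
        stages <- c(stages, list(list(
            name = "simulate",
            summary = sprintf("%d oligos, %d target chromosomes, %d cells",
                              nrow(lib), length(target),
                              length(unique(meas$cell_id))))))
    }

    aln <- with_stage("screen", {
        if (is.null(lib)) {
            if (is.null(config$library_path) ||
                !file.exists(config$library_path))
                stopf("oligo library not found: %s",
                      if (is.null(config$library_path)) "(no path)"
                      else config$library_path)
            lib <- read_oligo_library(config$library_path)
        }
        if (is.null(target)) {
            if (is.null(config$genome_path) ||
                !file.exists(config$genome_path))
                stopf("target genome not found: %s",
                      if (is.null(config$genome_path)) "(no path)"
                      else config$genome_path)
            target <- read_genome(config$genome_path)
        }
        a <- screen_library(lib, target, config$screen)
        if (config$write_files)
            write_hits_tsv(a, file.path(config$out_dir, "hits.tsv"))
        a
    })
    stages <- c(stages, list(list(
        name = "screen",
        summary = sprintf("%d retained hits from %d/%d oligos",
                          nrow(aln$hits), length(unique(aln$hits$oligo_id)),
                          sum(aln$set_sizes)))))

    prof <- with_stage("profile", {
        counts <- count_per_chromosome(aln)
        dens <- bin_density(aln, config$window_bp)
        calls <- call_signals(counts, config$thresholds, dens)
        codes <- barcode_chromosomes(calls,
                                     min_level = config$constraints$min_level)
        if (config$write_files) {
            write_count_matrix(counts,
                               file.path(config$out_dir, "counts.tsv"))
            write_density_bed(dens, file.path(config$out_dir, "density.bed"))
        }
        list(counts = counts, calls = calls, codes = codes)
    })
    ext <- matrix_extrema(prof$counts)
    stages <- c(stages, list(list(
        name = "profile",
        summary = sprintf("counts %d-%d; %d barcode collision group(s)",
                          ext$min_value, ext$max_value,
                          length(prof$codes$collisions)))))

    plan <- with_stage("plan", plan_rounds(prof$calls, config$constraints))
    if (config$write_files)
        jsonlite::write_json(
            list(rounds = plan$rounds, resolved = plan$resolved,
                 id_map = plan$id_map),
            file.path(config$out_dir, "plan.json"),
            auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stages <- c(stages, list(list(
        name = "plan",
        summary = sprintf("%d round(s), %d probe(s), resolved=%s",
                          length(plan$rounds), length(plan$probes),
                          plan$resolved))))

    kt <- NULL
    if (is.null(meas) && !is.null(config$measurements_path))
        meas <- with_stage("karyotype",
                           read_measurements(config$measurements_path))
    if (!is.null(meas)) {
        kt <- with_stage("karyotype", {
            k <- summarize_karyotype(meas, config$sim$ploidy)
            idio <- build_idiogram(k)
            if (config$write_files) {
                write_karyotype_json(k, file.path(config$out_dir,
                                                  "karyotype.json"))
                write_idiogram_svg(idio, file.path(config$out_dir,
                                                   "idiogram.svg"))
                write_idiogram_json(idio, file.path(config$out_dir,
                                                    "idiogram.json"))
            }
            k
        })
        stages <- c(stages, list(list(
            name = "karyotype",
            summary = sprintf("%d chromosome(s), total %.2f-%.2f um",
                              nrow(kt), min(kt$total_mean),
                              max(kt$total_mean)))))
    }

    report <- list(
        tool = "oligofish",
        version = as.character(packageVersion("oligofish")),
        seed = config$seed,
        parameters = list(
            min_match_bp = config$screen$min_match_bp,
            min_homology_frac = config$screen$min_homology_frac,
            mode = config$screen$mode,
            window_bp = config$window_bp,
            candidate_min = config$thresholds$candidate_min,
            confident_min = config$thresholds$confident_min,
            max_rounds = config$constraints$max_rounds),
        stages = stages,
        plan_resolved = plan$resolved)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
}
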