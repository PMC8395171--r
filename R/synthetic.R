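#' Divergence scenario
#'
#' A per-site substitution rate plus a descriptive label in million years
#' (MY).  Labels map to rates only through a user-chosen clock; no realism
#' is claimed.  The package ships three qualitative presets mirroring the
#' comparative-cytogenetics setting: closely related (~9 MY analog,
#' rate 0.05), painting-source to reference (~11.9 MY analog, rate 0.10)
#' and painting-source to distant polyploid (~18 MY analog, rate 0.20).
#'
#' @param name scenario label.
#' @param subs_per_site per-site substitution probability in `[0, 0.75]`.
#' @param label_my divergence-time label in MY (descriptive only).
#' @return A list of class `divergence_scenario`.
#' @export
divergence_scenario <- function(name = "reference-target",
                                subs_per_site = 0.10, label_my = 11.9) {
    if (!is.numeric(subs_per_site) || subs_per_site < 0 ||
        subs_per_site > 0.75)
        stopf("subs_per_site must be in [0, 0.75]")
    structure(list(name = name, subs_per_site = subs_per_site,
                   label_my = label_my), class = "divergence_scenario")
}

#' Simulation configuration
#'
#' Defaults describe the emulated study system: a 10-chromosome reference
#' genome (0.8-2.0 Mb per chromosome at desk scale), a 45-nt painting
#' library at 0.25 oligo per kb tiling every chromosome, a hexaploid
#' target (2n = 60, x = 10) diverged from the reference, and 10 metaphase
#' cells measured with 0.15 um Gaussian noise per arm.
#'
#' @param seed integer master seed; every generator output is a pure
#'   function of (config, seed).
#' @param n_chrom number of reference chromosomes.
#' @param chrom_lengths_bp chromosome lengths; default a deterministic
#'   ramp from 2.0 Mb down to 0.8 Mb.
#' @param oligo_len_nt oligo length (45 nt, consistent with a 32-bp
#'   70%-homology retention rule).
#' @param oligo_density_per_kb target library density.
#' @param scenario a [divergence_scenario()].
#' @param ploidy a [ploidy()] (default 2n = 60, x = 10).
#' @param measurement_noise_sd_um Gaussian noise SD per measured arm.
#' @param n_cells metaphase cells measured.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 10L, chrom_lengths_bp = NULL,
                       oligo_len_nt = 45L, oligo_density_per_kb = 0.25,
                       scenario = divergence_scenario(),
                       ploidy = oligofish::ploidy(60L, 10L),
                       measurement_noise_sd_um = 0.15, n_cells = 10L) {
    if (!is_count(seed)) stopf("seed must be an integer")
    if (!is_count(n_chrom) || n_chrom < 1) stopf("n_chrom must be >= 1")
    if (is.null(chrom_lengths_bp))
        chrom_lengths_bp <- as.integer(round(
            seq(2.0e6, 0.8e6, length.out = n_chrom)))
    chrom_lengths_bp <- as.integer(chrom_lengths_bp)
    if (length(chrom_lengths_bp) != n_chrom || any(chrom_lengths_bp < 1))
        stopf("chrom_lengths_bp must give %d positive lengths", n_chrom)
    if (!is_count(oligo_len_nt) || oligo_len_nt < 20)
        stopf("oligo_len_nt must be an integer >= 20")
    if (oligo_density_per_kb <= 0)
        stopf("oligo_density_per_kb must be positive")
    if (any(oligo_density_per_kb * chrom_lengths_bp / 1000 < 1))
        stopf("density x length must give >= 1 oligo per chromosome")
    stopifnot(inherits(scenario, "divergence_scenario"),
              inherits(ploidy, "ploidy"))
    if (measurement_noise_sd_um < 0) stopf("noise SD must be >= 0")
    if (!is_count(n_cells) || n_cells < 1) stopf("n_cells must be >= 1")
    structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                   chrom_lengths_bp = chrom_lengths_bp,
                   oligo_len_nt = as.integer(oligo_len_nt),
                   oligo_density_per_kb = oligo_density_per_kb,
                   scenario = scenario, ploidy = ploidy,
                   measurement_noise_sd_um = measurement_noise_sd_um,
                   n_cells = as.integer(n_cells)),
              class = "sim_config")
}

#' Simulate a reference genome
#'
#' I.i.d. uniform A/C/G/T per chromosome, seeded and reproducible.  Two
#' rDNA analog sites are recorded in the truth log as tagged intervals
#' (not repeat sequence): a 5S analog pericentromeric on the
#' ninth-from-largest chromosome and a 35S analog distal on the sixth,
#' mirroring the reference species' arrangement.
#'
#' @param config a [sim_config()].
#' @return List with `genome` (named `DNAStringSet`) and `truth` (list
#'   with `chrom_lengths` and `rdna_sites`).
#' @export
simulate_reference_genome <- function(config) {
    stopifnot(inherits(config, "sim_config"))
    set.seed(derive_seed(config$seed, 1L))
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(config$chrom_lengths_bp, function(L) {
        paste(sample(bases, L, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- paste0("refChr", seq_len(config$n_chrom))
    genome <- Biostrings::DNAStringSet(seqs)
    rdna <- NULL
    if (config$n_chrom >= 9) {
        l9 <- config$chrom_lengths_bp[9]
        l6 <- config$chrom_lengths_bp[6]
        rdna <- data.frame(
            name = c("5S", "35S"),
            chrom = c("refChr9", "refChr6"),
            start = as.integer(c(round(0.45 * l9), round(0.92 * l6))),
            end = as.integer(c(round(0.45 * l9) + 5000L,
                               round(0.92 * l6) + 5000L)),
            region = c("pericentromeric", "distal-long"),
            stringsAsFactors = FALSE)
    }
    list(genome = genome,
         truth = list(chrom_lengths = setNames(config$chrom_lengths_bp,
                                               names(seqs)),
                      rdna_sites = rdna))
}

#' Design a painting-oligo library from a genome
#'
#' Oligos are sampled at evenly spaced starts along each chromosome to the
#' target density, one probe set per source chromosome (`CP1`, `CP2`,
#' ...).  Oligos whose sequence occurs more than once in the genome on
#' either strand are discarded and locally resampled (single-copy
#' filter).
#'
#' @param genome named `DNAStringSet` (or coercible).
#' @param config a [sim_config()].
#' @return List with `library` (an [oligo_library()]) and `truth` (data
#'   frame of per-oligo source chromosome and 0-based start).
#' @export
design_oligo_library <- function(genome, config) {
    stopifnot(inherits(config, "sim_config"))
    g <- as_genome(genome)
    L_oligo <- config$oligo_len_nt
    if (L_oligo > min(Biostrings::width(g)))
        stopf("oligo length exceeds the shortest chromosome")
    ids <- character(0); sets <- character(0)
    seqs <- character(0); src_chrom <- character(0); src_start <- integer(0)
    for (i in seq_along(g)) {
        cn <- names(g)[i]
        L <- Biostrings::width(g)[i]
        n <- max(1L, as.integer(round(config$oligo_density_per_kb * L / 1000)))
        starts <- as.integer(floor(seq(0, L - L_oligo, length.out = n)))
        ids <- c(ids, sprintf("CP%d_%05d", i, seq_len(n)))
        sets <- c(sets, rep(sprintf("CP%d", i), n))
        seqs <- c(seqs, substring(as.character(g[[i]]), starts + 1,
                                  starts + L_oligo))
        src_chrom <- c(src_chrom, rep(cn, n))
        src_start <- c(src_start, starts)
    }
    # single-copy filter: total occurrences on either strand must be 1
    occurrences <- function(ss) {
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(ss))
        fw <- rowSums(Biostrings::vcountPDict(pd, g))
        rc <- Biostrings::reverseComplement(Biostrings::DNAStringSet(ss))
        rv <- rowSums(Biostrings::vcountPDict(Biostrings::PDict(rc), g))
        fw + rv
    }
    occ <- occurrences(seqs)
    for (attempt in 1:8) {
        bad <- which(occ != 1)
        if (length(bad) == 0) break
        # local resample: nudge the start by one oligo length per attempt
        for (b in bad) {
            Lc <- Biostrings::width(g)[match(src_chrom[b], names(g))]
            ns <- min(max(0L, src_start[b] + attempt * L_oligo),
                      Lc - L_oligo)
            src_start[b] <- as.integer(ns)
            seqs[b] <- substring(
                as.character(g[[match(src_chrom[b], names(g))]]),
                ns + 1, ns + L_oligo)
        }
        occ[bad] <- occurrences(seqs[bad])
    }
    keep <- occ == 1
    target <- length(seqs)
    if (sum(keep) < 0.8 * target)
        stopf("single-copy filtering left %d/%d oligos (achieved density %.3f/kb)",
              sum(keep), target,
              sum(keep) / (sum(Biostrings::width(g)) / 1000))
    lib <- oligo_library(ids[keep], sets[keep], seqs[keep])
    list(library = lib,
         truth = data.frame(oligo_id = ids[keep], chrom = src_chrom[keep],
                            start = src_start[keep],
                            stringsAsFactors = FALSE))
}

# encode/decode helpers for substitution simulation
seq_to_int <- function(s) {
    match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
}
int_to_seq <- function(v) paste(c("A", "C", "G", "T")[v + 1L], collapse = "")

#' Describe a segment translocation
#'
#' @param from,to source and destination chromosome names.
#' @param from_start,from_end 0-based half-open source interval.
#' @param to_pos 0-based insertion position in the destination.
#' @return A list of class `rearrangement`.
#' @export
translocation <- function(from, from_start, from_end, to, to_pos) {
    if (from_end <= from_start) stopf("empty translocation interval")
    structure(list(type = "translocation", from = from,
                   from_start = as.integer(from_start),
                   from_end = as.integer(from_end), to = to,
                   to_pos = as.integer(to_pos)), class = "rearrangement")
}

#' Diverge a genome by per-site substitution
#'
#' Each site is substituted independently with probability
#' `scenario$subs_per_site`, always to a different base.  Common random
#' numbers are used across rates: at a fixed seed the substituted site set
#' at a lower rate is a subset of that at any higher rate, so library
#' retention is non-increasing in the rate by construction.  Optional
#' translocations move tagged segments between chromosomes (recorded in
#' the truth log, and any rDNA analog site inside a moved segment moves
#' with it).
#'
#' @param genome named `DNAStringSet` (or coercible).
#' @param scenario a [divergence_scenario()].
#' @param rearrangements optional list of [translocation()]s.
#' @param seed integer seed.
#' @param rdna_sites optional rDNA truth table to be carried/updated.
#' @return List with `genome` (diverged `DNAStringSet`) and `truth` (list
#'   with `n_substitutions`, `rearrangements`, `rdna_sites`).
#' @export
diverge_genome <- function(genome, scenario = divergence_scenario(),
                           rearrangements = NULL, seed = 1L,
                           rdna_sites = NULL) {
    stopifnot(inherits(scenario, "divergence_scenario"))
    g <- as_genome(genome)
    rate <- scenario$subs_per_site
    set.seed(derive_seed(seed, 2L))
    out <- character(length(g))
    n_subs <- integer(length(g))
    for (i in seq_along(g)) {
        v <- seq_to_int(as.character(g[[i]]))
        u <- runif(length(v))
        shift <- sample(1:3, length(v), replace = TRUE)
        hit <- u < rate
        v[hit] <- (v[hit] + shift[hit]) %% 4L
        n_subs[i] <- sum(hit)
        out[i] <- int_to_seq(v)
    }
    names(out) <- names(g)
    if (!is.null(rearrangements)) {
        iv <- do.call(rbind, lapply(rearrangements, function(r)
            data.frame(chrom = r$from, start = r$from_start,
                       end = r$from_end)))
        for (cn in unique(iv$chrom)) {
            d <- iv[iv$chrom == cn, , drop = FALSE]
            d <- d[order(d$start), , drop = FALSE]
            if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
                stopf("overlapping rearrangement intervals on %s", cn)
        }
        for (r in rearrangements) {
            if (!r$from %in% names(out) || !r$to %in% names(out))
                stopf("translocation references unknown chromosome")
            seg <- substring(out[r$from], r$from_start + 1, r$from_end)
            out[r$from] <- paste0(
                substring(out[r$from], 1, r$from_start),
                substring(out[r$from], r$from_end + 1))
            out[r$to] <- paste0(
                substring(out[r$to], 1, r$to_pos), seg,
                substring(out[r$to], r$to_pos + 1))
            if (!is.null(rdna_sites)) {
                inside <- rdna_sites$chrom == r$from &
                    rdna_sites$start >= r$from_start &
                    rdna_sites$end <= r$from_end
                rdna_sites$chrom[inside] <- r$to
                rdna_sites$start[inside] <-
                    rdna_sites$start[inside] - r$from_start + r$to_pos
                rdna_sites$end[inside] <-
                    rdna_sites$end[inside] - r$from_start + r$to_pos
            }
        }
    }
    list(genome = Biostrings::DNAStringSet(out),
         truth = list(n_substitutions = setNames(n_subs, names(g)),
                      rearrangements = rearrangements,
                      rdna_sites = rdna_sites))
}

#' Expand a genome into a polyploid chromosome complement
#'
#' Each basic chromosome is copied `ploidy_level` times; each copy gets
#' independent low-rate jitter substitutions emulating homoeolog
#' divergence within the polyploid.
#'
#' @param genome named `DNAStringSet` (or coercible) of basic
#'   chromosomes.
#' @param ploidy a [ploidy()]; `x_basic` must equal the number of basic
#'   chromosomes.
#' @param per_copy_jitter_rate per-site substitution rate per copy.
#' @param seed integer seed.
#' @return List with `complement` (named `DNAStringSet` of `two_n`
#'   sequences, names `<chrom>_copy<j>`) and `truth` (data frame mapping
#'   each copy to its source chromosome and homoeologous group).
#' @export
polyploidize <- function(genome, ploidy = oligofish::ploidy(60L, 10L),
                         per_copy_jitter_rate = 0.005, seed = 1L) {
    stopifnot(inherits(ploidy, "ploidy"))
    g <- as_genome(genome)
    if (length(g) != ploidy$x_basic)
        stopf("genome has %d chromosomes but x_basic is %d",
              length(g), ploidy$x_basic)
    set.seed(derive_seed(seed, 3L))
    k <- ploidy$ploidy_level
    seqs <- character(0)
    truth <- NULL
    for (i in seq_along(g)) {
        v0 <- seq_to_int(as.character(g[[i]]))
        for (j in seq_len(k)) {
            v <- v0
            if (per_copy_jitter_rate > 0) {
                hit <- runif(length(v)) < per_copy_jitter_rate
                shift <- sample(1:3, sum(hit), replace = TRUE)
                v[hit] <- (v[hit] + shift) %% 4L
            }
            nm <- sprintf("%s_copy%d", names(g)[i], j)
            seqs[nm] <- int_to_seq(v)
            truth <- rbind(truth, data.frame(
                copy = nm, source_chrom = names(g)[i], group = i,
                stringsAsFactors = FALSE))
        }
    }
    list(complement = Biostrings::DNAStringSet(seqs), truth = truth)
}

#' Default true arm lengths for the measurement simulator
#'
#' A deterministic desk-scale karyotype: total lengths ramp from 3.6 um
#' down to 2.5 um and arm ratios from 1.45 to 2.2 (a metacentric to
#' submetacentric range with well-separated arms).
#'
#' @param n_chrom number of chromosomes.
#' @return Data frame with `chrom_label`, `long_um`, `short_um`.
#' @export
default_true_arms <- function(n_chrom = 10L) {
    total <- seq(3.6, 2.5, length.out = n_chrom)
    ratio <- seq(1.45, 2.2, length.out = n_chrom)
    short <- total / (1 + ratio)
    data.frame(chrom_label = paste0("chr", seq_len(n_chrom)),
               long_um = total - short, short_um = short,
               stringsAsFactors = FALSE)
}

#' Simulate noisy metaphase arm measurements
#'
#' Per cell and homolog copy, each arm is the true length plus independent
#' Gaussian noise (truncated positive); copies are dropped at
#' `missing_copy_rate`, and long/short ordering is enforced after noise
#' (as a microscopist would label the longer measured arm "long").
#'
#' @param true_arms data frame with `chrom_label`, `long_um`, `short_um`.
#' @param noise_sd Gaussian noise SD in um.
#' @param n_cells number of metaphase cells.
#' @param ploidy a [ploidy()]; `ploidy_level` homolog copies per cell.
#' @param missing_copy_rate probability a copy is missing from a cell.
#' @param seed integer seed.
#' @return Measurement data frame (`cell_id`, `chrom_label`,
#'   `long_arm_um`, `short_arm_um`), one row per measured copy, with the
#'   `true_arms` table attached as attribute `truth`.
#' @export
simulate_measurements <- function(true_arms, noise_sd = 0.15, n_cells = 10L,
                                  ploidy = oligofish::ploidy(60L, 10L),
                                  missing_copy_rate = 0, seed = 1L) {
    stopifnot(all(c("chrom_label", "long_um", "short_um") %in%
                  names(true_arms)))
    if (noise_sd < 0) stopf("noise_sd must be >= 0")
    set.seed(derive_seed(seed, 4L))
    k <- ploidy$ploidy_level
    rows <- vector("list", n_cells * nrow(true_arms))
    idx <- 0L
    for (cell in seq_len(n_cells)) {
        for (i in seq_len(nrow(true_arms))) {
            present <- runif(k) >= missing_copy_rate
            n <- sum(present)
            if (n == 0) next
            lg <- true_arms$long_um[i] + rnorm(n, 0, noise_sd)
            sh <- true_arms$short_um[i] + rnorm(n, 0, noise_sd)
            lg <- pmax(lg, 0.01)
            sh <- pmax(sh, 0.01)
            swap <- sh > lg
            tmp <- lg[swap]; lg[swap] <- sh[swap]; sh[swap] <- tmp
            idx <- idx + 1L
            rows[[idx]] <- data.frame(
                cell_id = sprintf("cell%02d", cell),
                chrom_label = true_arms$chrom_label[i],
                long_arm_um = lg, short_arm_um = sh,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows[seq_len(idx)])
    rownames(out) <- NULL
    attr(out, "truth") <- true_arms
    out
}
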