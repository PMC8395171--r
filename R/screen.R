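#' Screening parameters
#'
#' Controls the oligo-to-genome screen.  The retention rule keeps a hit
#' when its matched bases reach both an absolute floor (`min_match_bp`,
#' default 32 bp) and a fraction of the oligo length
#' (`min_homology_frac`, default 0.70); for the default 45-nt oligos the
#' two coincide (ceil(0.70 x 45) = 32).
#'
#' Two search modes are offered.  `"seed"` is classic seed-and-extend over
#' an exact k-mer index: fast at genome scale but, like every heuristic
#' seeded aligner, it can miss a qualifying placement that contains no
#' exact `seed_k`-mer.  `"exhaustive"` scores every full-length ungapped
#' placement on both strands and is complete with respect to the retention
#' rule; use it when completeness matters (small genomes, calibration
#' against closed-form expectations).
#'
#' @param seed_k exact seed length for `"seed"` mode (8-31; must not
#'   exceed `min_match_bp`).
#' @param min_match_bp absolute matched-bases floor.
#' @param min_homology_frac required matched fraction of the oligo length.
#' @param max_hits_per_oligo cap on retained hits returned per oligo
#'   (best by matched bases; ties by chromosome name then start).
#' @param mode `"seed"` or `"exhaustive"`.
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(seed_k = 16L, min_match_bp = 32L,
                          min_homology_frac = 0.70,
                          max_hits_per_oligo = 50L,
                          mode = c("seed", "exhaustive")) {
    mode <- match.arg(mode)
    if (!is_count(seed_k) || seed_k < 8 || seed_k > 31)
        stopf("seed_k must be an integer in 8..31")
    if (!is_count(min_match_bp) || min_match_bp < 1)
        stopf("min_match_bp must be a positive integer")
    if (!is.numeric(min_homology_frac) || min_homology_frac <= 0 ||
        min_homology_frac > 1)
        stopf("min_homology_frac must be in (0, 1]")
    if (seed_k > min_match_bp)
        stopf("seed_k (%d) must not exceed min_match_bp (%d)",
              seed_k, min_match_bp)
    if (!is_count(max_hits_per_oligo) || max_hits_per_oligo < 1)
        stopf("max_hits_per_oligo must be a positive integer")
    structure(list(seed_k = as.integer(seed_k),
                   min_match_bp = as.integer(min_match_bp),
                   min_homology_frac = min_homology_frac,
                   max_hits_per_oligo = as.integer(max_hits_per_oligo),
                   mode = mode),
              class = "screen_params")
}

#' Build an exact k-mer seed index over a genome
#'
#' The index maps every exact k-mer to its (chromosome, position, strand)
#' occurrences on both strands; minus-strand occurrences are reported at
#' the plus-strand coordinates of the reverse-complement site.
#'
#' @param genome named `DNAStringSet`, named character vector, or FASTA
#'   path.
#' @param k seed length (screening itself requires 8-31, but shorter
#'   seeds are allowed for interactive queries).
#' @return An object of class `seed_index`.
#' @export
build_seed_index <- function(genome, k = 16L) {
    g <- as_genome(genome)
    if (!is_count(k) || k < 1) stopf("k must be a positive integer")
    if (k > max(Biostrings::width(g)))
        stopf("k (%d) exceeds the longest chromosome (%d bp)",
              k, max(Biostrings::width(g)))
    structure(list(genome = g, k = as.integer(k)), class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
    cat(sprintf("seed index: k=%d over %d chromosome(s), %d bp total\n",
                x$k, length(x$genome), sum(Biostrings::width(x$genome))))
    invisible(x)
}

#' Query a seed index for one k-mer
#'
#' @param index a [build_seed_index()] object.
#' @param kmer character k-mer of the index's seed length.
#' @return Data frame with columns `chrom`, `pos` (0-based), `strand`.
#' @export
query_seed <- function(index, kmer) {
    stopifnot(inherits(index, "seed_index"))
    kmer <- toupper(kmer)
    if (nchar(kmer) != index$k)
        stopf("kmer length %d != index k %d", nchar(kmer), index$k)
    hit_pos <- function(pat) {
        m <- Biostrings::vmatchPattern(pat, index$genome)
        do.call(rbind, lapply(seq_along(m), function(i) {
            st <- Biostrings::start(m[[i]])
            if (length(st) == 0) return(NULL)
            data.frame(chrom = names(index$genome)[i], pos = st - 1L,
                       stringsAsFactors = FALSE)
        }))
    }
    plus <- hit_pos(kmer)
    rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(kmer)))
    minus <- hit_pos(rc)
    out <- rbind(
        if (!is.null(plus)) cbind(plus, strand = "+"),
        if (!is.null(minus)) cbind(minus, strand = "-"))
    if (is.null(out))
        return(data.frame(chrom = character(), pos = integer(),
                          strand = character(), stringsAsFactors = FALSE))
    out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# shared core: run the C++ screen and decorate the hit table
screen_core <- function(lib, genome, params) {
    g <- as_genome(genome)
    raw <- cpp_screen(names(g), as.character(g), lib$sequence,
                      params$seed_k, params$min_match_bp,
                      params$min_homology_frac, params$max_hits_per_oligo,
                      params$mode == "exhaustive")
    hits <- data.frame(
        oligo_id = lib$oligo_id[raw$oligo],
        probe_set = lib$probe_set[raw$oligo],
        chrom = names(g)[raw$chrom_idx],
        start = raw$start,
        end = raw$start + raw$span_bp,
        strand = raw$strand,
        matched_bases = raw$matched_bases,
        span_bp = raw$span_bp,
        identity = raw$matched_bases / lib$length[raw$oligo],
        stringsAsFactors = FALSE)
    list(hits = hits, genome = g)
}

#' Align one oligo against an indexed genome
#'
#' Seed-and-extend without gaps: each exact seed match defines a diagonal;
#' the full-length ungapped placement of the oligo on that diagonal is
#' scored (ambiguous bases count as mismatches), seeds sharing a
#' (chromosome, strand, diagonal) are merged into one hit, and hits
#' meeting the retention rule are returned, best first.  With
#' `params$mode = "exhaustive"` every diagonal is scored instead of only
#' the seeded ones.
#'
#' @param oligo single-row [oligo_library()], or a character sequence.
#' @param index a [build_seed_index()] object.
#' @param params [screen_params()]; the index's own `k` is used for
#'   seeding.
#' @return Data frame of retained hits (possibly empty) with columns
#'   `oligo_id`, `chrom`, `start`, `end`, `strand`, `matched_bases`,
#'   `span_bp`, `identity`.
#' @export
align_oligo <- function(oligo, index, params = screen_params()) {
    stopifnot(inherits(index, "seed_index"), inherits(params, "screen_params"))
    if (is.character(oligo))
        oligo <- oligo_library("oligo_1", "set", oligo)
    stopifnot(inherits(oligo, "oligo_library"), nrow(oligo) == 1)
    if (oligo$length < params$min_match_bp)
        stopf("oligo %s (%d nt) is shorter than min_match_bp (%d)",
              oligo$oligo_id, oligo$length, params$min_match_bp)
    p <- params
    p$seed_k <- index$k
    screen_core(oligo, index$genome, p)$hits[, c(
        "oligo_id", "chrom", "start", "end", "strand", "matched_bases",
        "span_bp", "identity")]
}

#' Screen an oligo library against a target genome
#'
#' Aligns every oligo on both strands, applies the retention rule, and
#' returns the retained hit set together with per-probe-set retention
#' totals.  Deterministic for identical inputs and parameters.
#'
#' @param library an [oligo_library()].
#' @param genome named `DNAStringSet`, named character vector, or FASTA
#'   path.
#' @param params [screen_params()].
#' @param library_id,genome_id optional labels recorded on the result.
#' @return An object of class `alignment_set`: list with `hits` (data
#'   frame), `params`, `chrom_lengths`, `set_sizes`, `retained_per_set`,
#'   `library_id`, `genome_id`.
#' @export
screen_library <- function(library, genome, params = screen_params(),
                           library_id = "library", genome_id = "genome") {
    stopifnot(inherits(library, "oligo_library"),
              inherits(params, "screen_params"))
    if (nrow(library) == 0) stopf("oligo library is empty")
    if (any(library$length < params$min_match_bp))
        stopf("library contains oligos shorter than min_match_bp (%d)",
              params$min_match_bp)
    core <- screen_core(library, genome, params)
    g <- core$genome
    sets <- unique(library$probe_set)
    set_sizes <- setNames(as.integer(table(library$probe_set)[sets]), sets)
    retained <- vapply(sets, function(s) {
        length(unique(core$hits$oligo_id[core$hits$probe_set == s]))
    }, integer(1))
    structure(list(
        hits = core$hits,
        params = params,
        chrom_lengths = setNames(Biostrings::width(g), names(g)),
        set_sizes = set_sizes,
        retained_per_set = setNames(retained, sets),
        library_id = library_id,
        genome_id = genome_id), class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
    cat(sprintf(
        "alignment set: %d retained hits, %d/%d oligos with >=1 hit\n",
        nrow(x$hits), length(unique(x$hits$oligo_id)), sum(x$set_sizes)))
    cat(sprintf("  retention rule: >= max(%d bp, %.0f%% of oligo) matched, mode '%s'\n",
                x$params$min_match_bp, 100 * x$params$min_homology_frac,
                x$params$mode))
    df <- data.frame(probe_set = names(x$set_sizes),
                     oligos = as.integer(x$set_sizes),
                     retained = as.integer(x$retained_per_set))
    print(df, row.names = FALSE)
    invisible(x)
}

#' Write retained hits as TSV
#'
#' Columns: oligo_id, probe_set, chrom, start, end, strand,
#' matched_bases, identity.  Byte-identical for identical alignment sets.
#'
#' @param aln an `alignment_set`.
#' @param path output file.
#' @export
write_hits_tsv <- function(aln, path) {
    stopifnot(inherits(aln, "alignment_set"))
    df <- aln$hits[, c("oligo_id", "probe_set", "chrom", "start", "end",
                       "strand", "matched_bases", "identity")]
    df$identity <- sprintf("%.6f", df$identity)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
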