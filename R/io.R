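#' Construct an oligo painting library
#'
#' An oligo library is a set of short probe sequences grouped into probe
#' sets (one pooled painting probe per source chromosome).  Sequences must
#' be DNA over A/C/G/T/N, at least 20 nt long, with unique identifiers.
#'
#' @param oligo_id character vector of unique oligo identifiers.
#' @param probe_set character vector of probe-set labels (recycled if
#'   length 1).
#' @param sequence character vector of DNA sequences.
#' @return A data frame of class `oligo_library` with columns `oligo_id`,
#'   `probe_set`, `sequence`, `length`.
#' @export
oligo_library <- function(oligo_id, probe_set, sequence) {
    oligo_id <- as.character(oligo_id)
    sequence <- toupper(as.character(sequence))
    if (length(probe_set) == 1) probe_set <- rep(probe_set, length(oligo_id))
    probe_set <- as.character(probe_set)
    if (length(oligo_id) == 0) stopf("oligo library is empty")
    if (length(sequence) != length(oligo_id) ||
        length(probe_set) != length(oligo_id))
        stopf("oligo_id, probe_set and sequence lengths differ")
    if (anyDuplicated(oligo_id))
        stopf("duplicate oligo ID: %s", oligo_id[duplicated(oligo_id)][1])
    if (any(is.na(probe_set) | probe_set == ""))
        stopf("probe_set labels must be non-empty")
    bad <- grepl("[^ACGTN]", sequence)
    if (any(bad))
        stopf("oligo %s contains characters outside A/C/G/T/N",
              oligo_id[bad][1])
    len <- nchar(sequence)
    if (any(len < 20))
        stopf("oligo %s is shorter than 20 nt", oligo_id[len < 20][1])
    out <- data.frame(oligo_id = oligo_id, probe_set = probe_set,
                      sequence = sequence, length = len,
                      stringsAsFactors = FALSE)
    class(out) <- c("oligo_library", "data.frame")
    out
}

#' Read an oligo painting library from FASTA
#'
#' Record identifiers encode the probe set as a prefix before
#' `set_delimiter` (for example `CP1_00042` belongs to probe set `CP1`).
#'
#' @param path FASTA file (optionally gzip compressed).
#' @param set_delimiter delimiter separating the probe-set prefix from the
#'   rest of the identifier.
#' @return An [oligo_library()] object.
#' @export
read_oligo_library <- function(path, set_delimiter = "_") {
    if (!file.exists(path)) stopf("file not found: %s", path)
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    if (length(first) == 0) stopf("empty oligo library: %s", path)
    if (!startsWith(first[1], ">"))
        stopf("malformed FASTA at line 1 of %s: expected '>'", path)
    seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                     error = function(e)
                         stopf("malformed FASTA in %s: %s", path,
                               conditionMessage(e)))
    if (length(seqs) == 0) stopf("empty oligo library: %s", path)
    ids <- sub("\\s.*$", "", names(seqs))
    has_delim <- grepl(set_delimiter, ids, fixed = TRUE)
    if (!all(has_delim))
        stopf("record '%s' does not encode a probe set before '%s'",
              ids[!has_delim][1], set_delimiter)
    sets <- vapply(strsplit(ids, set_delimiter, fixed = TRUE),
                   `[`, character(1), 1L)
    oligo_library(ids, sets, as.character(seqs))
}

#' Write an oligo library to FASTA
#'
#' @param library an [oligo_library()].
#' @param path output file.
#' @export
write_oligo_library <- function(library, path) {
    stopifnot(inherits(library, "oligo_library"))
    x <- Biostrings::DNAStringSet(library$sequence)
    names(x) <- library$oligo_id
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' @export
print.oligo_library <- function(x, ...) {
    cat(sprintf("oligo library: %d oligos in %d probe sets (%d-%d nt)\n",
                nrow(x), length(unique(x$probe_set)),
                min(x$length), max(x$length)))
    tab <- table(x$probe_set)
    print(tab[order(natural_order(names(tab)))])
    invisible(x)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file (optionally gzip compressed).
#' @return A named `DNAStringSet`.
#' @export
read_genome <- function(path) as_genome(path)

#' Write a genome to FASTA
#'
#' @param genome named `DNAStringSet` or named character vector.
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
    Biostrings::writeXStringSet(as_genome(genome), path)
    invisible(path)
}

#' Read a probe-set-by-chromosome count matrix
#'
#' Tab-separated with probe-set row labels in the first column and
#' chromosome column labels in the header.  Thousands separators
#' ("27,169") are accepted on input and never written back.
#'
#' @param path TSV file.
#' @return An integer matrix of class `count_matrix`.
#' @export
read_count_matrix <- function(path) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                      stringsAsFactors = FALSE)
    if (ncol(raw) < 2) stopf("count matrix needs row labels and >=1 column")
    rn <- raw[[1]]
    cells <- as.matrix(raw[, -1, drop = FALSE])
    cells <- gsub(",", "", trimws(cells), fixed = TRUE)
    bad <- !grepl("^[0-9]+$", cells)
    if (any(bad))
        stopf("invalid count matrix cell '%s' at (%s, %s)",
              cells[bad][1], rn[row(cells)[bad][1]],
              colnames(cells)[col(cells)[bad][1]])
    m <- matrix(as.integer(cells), nrow = nrow(cells),
                dimnames = list(rn, colnames(cells)))
    count_matrix(m)
}

#' Validate a count matrix
#'
#' @param m integer matrix with probe-set rows and chromosome columns.
#' @return `m` with class `count_matrix`.
#' @export
count_matrix <- function(m) {
    if (!is.matrix(m)) stopf("count matrix must be a matrix")
    if (ncol(m) == 0) stopf("count matrix has no chromosome columns")
    if (is.null(colnames(m)) || (nrow(m) > 0 && is.null(rownames(m))))
        stopf("count matrix must have row and column labels")
    if (anyNA(m) || any(m < 0) || any(m != as.integer(m)))
        stopf("count matrix cells must be non-negative integers")
    storage.mode(m) <- "integer"
    class(m) <- c("count_matrix", class(matrix()))
    m
}

#' Write a count matrix as TSV
#'
#' @param m a `count_matrix`.
#' @param path output file.
#' @export
write_count_matrix <- function(m, path) {
    df <- data.frame(probe_set = rownames(m), as.data.frame(unclass(m)),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Construct a windowed probe density profile
#'
#' Per (probe set, chromosome) counts of retained alignment loci in
#' consecutive fixed-width windows.  Windows are 0-based half-open; the
#' last window of each chromosome may be shorter than `window_bp` and is
#' always present, so per-chromosome windows tile the whole sequence.
#'
#' @param chrom,start,end,probe_set,count parallel vectors of window rows.
#' @param window_bp nominal window width in bp.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return A data frame of class `density_profile`.
#' @export
density_profile <- function(chrom, start, end, probe_set, count,
                            window_bp, chrom_lengths = NULL) {
    df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                     end = as.integer(end),
                     probe_set = as.character(probe_set),
                     count = as.integer(count), stringsAsFactors = FALSE)
    if (nrow(df) == 0) stopf("density profile is empty")
    if (any(df$end <= df$start)) stopf("window end must exceed start")
    if (any(df$count < 0)) stopf("window counts must be non-negative")
    if (is.null(chrom_lengths)) {
        chrom_lengths <- tapply(df$end, df$chrom, max)
        chrom_lengths <- setNames(as.integer(chrom_lengths),
                                  names(chrom_lengths))
    }
    df <- df[order(df$chrom, df$start, df$probe_set), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "window_bp") <- as.integer(window_bp)
    attr(df, "chrom_lengths") <- chrom_lengths
    class(df) <- c("density_profile", "data.frame")
    df
}

#' Write a density profile as BED5-like text
#'
#' Five tab-separated columns (chrom, start, end, probe_set, count),
#' 0-based half-open, sorted by chromosome then start, no header.
#'
#' @param profile a [density_profile()].
#' @param path output file.
#' @export
write_density_bed <- function(profile, path) {
    stopifnot(inherits(profile, "density_profile"))
    if (nrow(profile) == 0) stopf("density profile is empty")
    ord <- order(profile$chrom, profile$start, profile$probe_set)
    df <- profile[ord, c("chrom", "start", "end", "probe_set", "count")]
    con <- tryCatch(file(path, "w"),
                    error = function(e) stopf("cannot write %s: %s", path,
                                              conditionMessage(e)))
    on.exit(close(con))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d", df$chrom, df$start, df$end,
                       df$probe_set, df$count), con)
    invisible(path)
}

#' Read a BED5-like density profile
#'
#' @param path BED file written by [write_density_bed()].
#' @param window_bp nominal window width; inferred from the widest window
#'   when omitted.
#' @return A [density_profile()].
#' @export
read_density_bed <- function(path, window_bp = NULL) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                     col.names = c("chrom", "start", "end", "probe_set",
                                   "count"))
    if (is.null(window_bp)) window_bp <- max(df$end - df$start)
    density_profile(df$chrom, df$start, df$end, df$probe_set, df$count,
                    window_bp)
}

#' Read per-cell chromosome arm measurements
#'
#' Tab-separated with header `cell_id`, `chrom_label`, `long_arm_um`,
#' `short_arm_um`; one row per measured homolog copy.
#'
#' @param path TSV file.
#' @return A data frame of measurement records.
#' @export
read_measurements <- function(path) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("cell_id", "chrom_label", "long_arm_um", "short_arm_um")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stopf("measurement table lacks column(s): %s",
              paste(miss, collapse = ", "))
    df <- df[, need]
    if (anyNA(df$long_arm_um) || anyNA(df$short_arm_um) ||
        any(df$long_arm_um <= 0) || any(df$short_arm_um <= 0))
        stopf("arm lengths must be positive")
    df
}

#' Write per-cell arm measurements as TSV
#'
#' @param measurements measurement data frame.
#' @param path output file.
#' @export
write_measurements <- function(measurements, path) {
    write.table(measurements, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Packaged published probe-count matrix
#'
#' The published alignment-count matrix of ten maize chromosome-painting
#' probe sets (MCP1-MCP10) against the ten sorghum chromosomes, shipped as
#' a plain-text fixture.
#'
#' @return A `count_matrix` (10 probe sets x 10 chromosomes).
#' @export
sorghum_mcp_counts <- function() {
    read_count_matrix(system.file("extdata", "sorghum_mcp_counts.tsv",
                                  package = "oligofish", mustWork = TRUE))
}

#' Packaged published karyotype table
#'
#' Published metaphase karyotype summary (arm means, SDs and arm ratios in
#' micrometres) for a hexaploid wild sugarcane relative, shipped as a
#' plain-text fixture.
#'
#' @return A data frame with one row per chromosome.
#' @export
tripidium_karyotype <- function() {
    read.delim(system.file("extdata", "tripidium_karyotype.tsv",
                           package = "oligofish", mustWork = TRUE),
               stringsAsFactors = FALSE)
}
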