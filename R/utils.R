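# shared internal helpers

# round half away from zero at `digits`, matching how karyotype tables are
# conventionally printed (base round() is half-to-even)
round_half_up <- function(x, digits = 2) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

# natural ordering for chromosome labels: "chr2" before "chr10"
natural_order <- function(x) {
    x <- as.character(x)
    num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", x)))
    pre <- gsub("[0-9]+", "", x)
    order(pre, num, x, na.last = TRUE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
    x == as.integer(x)

# coerce various genome representations to a named DNAStringSet
as_genome <- function(genome) {
    if (inherits(genome, "DNAStringSet")) {
        g <- genome
    } else if (is.character(genome) && length(genome) == 1 &&
               file.exists(genome)) {
        g <- Biostrings::readDNAStringSet(genome)
    } else if (is.character(genome)) {
        g <- Biostrings::DNAStringSet(toupper(genome))
    } else {
        stopf("cannot interpret object of class '%s' as a genome",
              class(genome)[1])
    }
    if (length(g) == 0) stopf("genome is empty")
    if (is.null(names(g)) || anyNA(names(g)) || any(names(g) == ""))
        stopf("genome sequences must be named")
    names(g) <- sub("\\s.*$", "", names(g))
    if (anyDuplicated(names(g)))
        stopf("duplicate chromosome name: %s",
              names(g)[duplicated(names(g))][1])
    g
}

# derive a reproducible 32-bit sub-seed for a pipeline stage
derive_seed <- function(seed, offset) {
    as.integer((as.double(seed) * 48271 + offset * 9973) %% 2147483647)
}
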