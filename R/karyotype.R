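#' Ploidy descriptor
#'
#' @param two_n somatic chromosome number (2n).
#' @param x_basic basic (monoploid) chromosome number (x).
#' @return A list of class `ploidy` with `two_n`, `x_basic`,
#'   `ploidy_level`.
#' @export
ploidy <- function(two_n = 60L, x_basic = 10L) {
    if (!is_count(two_n) || !is_count(x_basic) || two_n < 1 || x_basic < 1)
        stopf("two_n and x_basic must be positive integers")
    if (two_n %% x_basic != 0)
        stopf("two_n (%d) must be divisible by x_basic (%d)", two_n, x_basic)
    structure(list(two_n = as.integer(two_n), x_basic = as.integer(x_basic),
                   ploidy_level = as.integer(two_n / x_basic)),
              class = "ploidy")
}

#' Classify centromere position from the arm ratio
#'
#' Conventional (Levan-style) classes on the long/short arm ratio:
#' metacentric (m) up to 1.7 inclusive, submetacentric (sm) up to 3.0,
#' subtelocentric (st) up to 7.0, telocentric (t) beyond.  Boundaries are
#' configurable.
#'
#' @param ratio numeric vector of arm ratios (>= 1).
#' @param boundaries named upper bounds for classes m, sm, st.
#' @return Character vector over `{"m","sm","st","t"}`.
#' @export
classify_centromere <- function(ratio,
                                boundaries = c(m = 1.7, sm = 3.0, st = 7.0)) {
    if (any(is.na(ratio)) || any(ratio < 1))
        stopf("arm ratio must be >= 1")
    stopifnot(all(c("m", "sm", "st") %in% names(boundaries)),
              boundaries[["m"]] < boundaries[["sm"]],
              boundaries[["sm"]] < boundaries[["st"]])
    unname(ifelse(ratio <= boundaries[["m"]], "m",
                  ifelse(ratio <= boundaries[["sm"]], "sm",
                         ifelse(ratio <= boundaries[["st"]], "st", "t"))))
}

#' Summarize per-cell arm measurements into a karyotype table
#'
#' Homolog copies within a cell are averaged first, so cells missing a
#' copy remain comparable; statistics are then taken across cells.  The
#' per-cell total is long + short of the cell-averaged arms and the
#' per-cell ratio is long/short of the cell-averaged arms; reported means
#' are means of the per-cell values (mean of per-cell ratios, not the
#' ratio of mean arms).  Records with short > long are swapped with a
#' warning.
#'
#' @param measurements data frame with `cell_id`, `chrom_label`,
#'   `long_arm_um`, `short_arm_um` (one row per measured homolog copy).
#' @param ploidy optional [ploidy()] recorded on the result.
#' @param chrom_labels optional vector of expected labels; any other label
#'   in the data is an error.
#' @param boundaries centromere class boundaries, see
#'   [classify_centromere()].
#' @return A data frame of class `karyotype` with per-chromosome columns
#'   `n_cells`, `long_mean`, `long_sd`, `short_mean`, `short_sd`,
#'   `total_mean`, `total_sd`, `ratio_mean`, `ratio_sd`,
#'   `centromere_class`, in natural label order.
#' @export
summarize_karyotype <- function(measurements, ploidy = NULL,
                                chrom_labels = NULL,
                                boundaries = c(m = 1.7, sm = 3.0, st = 7.0)) {
    need <- c("cell_id", "chrom_label", "long_arm_um", "short_arm_um")
    miss <- setdiff(need, names(measurements))
    if (length(miss))
        stopf("measurements lack column(s): %s", paste(miss, collapse = ", "))
    m <- measurements[, need]
    if (nrow(m) == 0) stopf("no measurement records")
    if (anyNA(m$long_arm_um) || anyNA(m$short_arm_um) ||
        any(m$long_arm_um <= 0) || any(m$short_arm_um <= 0))
        stopf("arm lengths must be positive")
    if (!is.null(chrom_labels)) {
        unknown <- setdiff(unique(m$chrom_label), chrom_labels)
        if (length(unknown))
            stopf("unknown chromosome label: %s", unknown[1])
    }
    swap <- m$short_arm_um > m$long_arm_um
    if (any(swap)) {
        warning(sprintf("%d record(s) had short > long; arms swapped",
                        sum(swap)), call. = FALSE)
        tmp <- m$long_arm_um[swap]
        m$long_arm_um[swap] <- m$short_arm_um[swap]
        m$short_arm_um[swap] <- tmp
    }
    # homolog copies averaged within each cell first
    cell <- aggregate(cbind(long_arm_um, short_arm_um) ~
                          cell_id + chrom_label, data = m, FUN = mean)
    cell$total <- cell$long_arm_um + cell$short_arm_um
    cell$ratio <- cell$long_arm_um / cell$short_arm_um
    labs <- unique(cell$chrom_label)
    labs <- labs[natural_order(labs)]
    rows <- lapply(labs, function(cn) {
        d <- cell[cell$chrom_label == cn, , drop = FALSE]
        data.frame(chrom_label = cn, n_cells = nrow(d),
                   long_mean = mean(d$long_arm_um),
                   long_sd = sd(d$long_arm_um),
                   short_mean = mean(d$short_arm_um),
                   short_sd = sd(d$short_arm_um),
                   total_mean = mean(d$total), total_sd = sd(d$total),
                   ratio_mean = mean(d$ratio), ratio_sd = sd(d$ratio),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$centromere_class <- classify_centromere(out$ratio_mean, boundaries)
    attr(out, "ploidy") <- ploidy
    class(out) <- c("karyotype", "data.frame")
    out
}

#' @export
print.karyotype <- function(x, digits = 2, ...) {
    df <- as.data.frame(x)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) round_half_up(v, digits))
    cat(sprintf("karyotype: %d chromosome(s), measurements in um\n", nrow(df)))
    print(df, row.names = FALSE)
    invisible(x)
}

#' Write a karyotype table as JSON
#'
#' Values are reported rounded half-up to 2 decimals, matching the
#' conventional presentation of metaphase measurements.
#'
#' @param karyotype a `karyotype`.
#' @param path output file.
#' @export
write_karyotype_json <- function(karyotype, path) {
    df <- as.data.frame(karyotype)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) round_half_up(v, 2))
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Map target chromosomes to reference numbering by barcode identity
#'
#' Each target chromosome receives the reference chromosome label whose
#' binary barcode over the shared probe rows matches exactly.  Targets
#' with an all-zero barcode, with no match, or with several matching
#' references are flagged, never silently assigned.  Several targets
#' mapping to one reference is reported (expected for homoeologous groups
#' of a polyploid, suspicious otherwise).
#'
#' @param target_calls,reference_calls `signal_call` objects with the
#'   same probe rows.
#' @param min_level barcode bit cutoff, see [barcode_chromosomes()].
#' @return Data frame with `target`, `assigned_ref`, `status` in
#'   `{"matched","unassigned","ambiguous"}`; attribute `shared_refs`
#'   lists references matched by more than one target.
#' @export
assign_reference_numbers <- function(target_calls, reference_calls,
                                     min_level = c("uncertain", "present")) {
    min_level <- match.arg(min_level)
    stopifnot(inherits(target_calls, "signal_call"),
              inherits(reference_calls, "signal_call"))
    probes <- rownames(reference_calls$levels)
    if (!identical(sort(probes), sort(rownames(target_calls$levels))))
        stopf("target and reference calls must share the same probe rows")
    tb <- barcode_chromosomes(target_calls, probes, min_level)$barcodes
    rb <- barcode_chromosomes(reference_calls, probes, min_level)$barcodes
    tkey <- apply(tb, 1, paste, collapse = "")
    rkey <- apply(rb, 1, paste, collapse = "")
    zero <- paste(rep("0", length(probes)), collapse = "")
    assigned <- character(nrow(tb))
    status <- character(nrow(tb))
    for (i in seq_len(nrow(tb))) {
        if (tkey[i] == zero) {
            assigned[i] <- NA_character_; status[i] <- "unassigned"
        } else {
            hit <- names(rkey)[rkey == tkey[i]]
            if (length(hit) == 1) {
                assigned[i] <- hit; status[i] <- "matched"
            } else if (length(hit) == 0) {
                assigned[i] <- NA_character_; status[i] <- "unassigned"
            } else {
                assigned[i] <- NA_character_; status[i] <- "ambiguous"
            }
        }
    }
    out <- data.frame(target = rownames(tb), assigned_ref = assigned,
                      status = status, stringsAsFactors = FALSE)
    tab <- table(out$assigned_ref)
    attr(out, "shared_refs") <- names(tab)[tab > 1]
    out
}

#' Build an idiogram from a karyotype table
#'
#' Chromosome bars are drawn to scale (lengths proportional to
#' `total_mean`), short arm up, centromere at the arm boundary.
#' Annotation tracks attach a probe (or probe combination) with a colour
#' to a region of a chromosome: `whole`, `distal-long`, `distal-short` or
#' `pericentromeric`.
#'
#' @param karyotype a `karyotype` table.
#' @param annotations optional data frame with `chrom`, `label`, `color`,
#'   `region`.
#' @return An object of class `idiogram`.
#' @export
build_idiogram <- function(karyotype, annotations = NULL) {
    stopifnot(inherits(karyotype, "karyotype"))
    if (nrow(karyotype) == 0) stopf("karyotype is empty")
    regions <- c("whole", "distal-long", "distal-short", "pericentromeric")
    if (!is.null(annotations)) {
        need <- c("chrom", "label", "color", "region")
        miss <- setdiff(need, names(annotations))
        if (length(miss))
            stopf("annotations lack column(s): %s",
                  paste(miss, collapse = ", "))
        bad <- setdiff(unique(annotations$chrom), karyotype$chrom_label)
        if (length(bad))
            stopf("annotation references missing chromosome: %s", bad[1])
        badr <- setdiff(unique(annotations$region), regions)
        if (length(badr)) stopf("unknown annotation region: %s", badr[1])
    }
    structure(list(karyotype = as.data.frame(karyotype),
                   annotations = annotations), class = "idiogram")
}

#' @export
print.idiogram <- function(x, ...) {
    cat(sprintf("idiogram: %d chromosome(s), %d annotation(s)\n",
                nrow(x$karyotype),
                if (is.null(x$annotations)) 0L else nrow(x$annotations)))
    invisible(x)
}

# y-extent of an annotation region on one bar (short arm on top)
region_extent <- function(region, short_px, total_px) {
    long_px <- total_px - short_px
    switch(region,
           "whole" = c(0, total_px),
           "distal-short" = c(0, 0.25 * short_px),
           "distal-long" = c(total_px - 0.25 * long_px, total_px),
           "pericentromeric" = c(short_px - 0.15 * short_px,
                                 short_px + 0.15 * long_px))
}

#' Export an idiogram as SVG
#'
#' Deterministic text output: identical input produces byte-identical
#' files.
#'
#' @param idiogram an [build_idiogram()] object.
#' @param path output SVG file.
#' @export
write_idiogram_svg <- function(idiogram, path) {
    stopifnot(inherits(idiogram, "idiogram"))
    kt <- idiogram$karyotype
    kt <- kt[natural_order(kt$chrom_label), , drop = FALSE]
    n <- nrow(kt)
    bar_w <- 26; gap <- 34; top <- 40; max_h <- 300
    scale <- max_h / max(kt$total_mean)
    width <- 30 + n * (bar_w + gap)
    height <- top + max_h + 60
    ln <- c(sprintf(
        '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
        width, height),
        '<rect width="100%" height="100%" fill="white"/>')
    for (i in seq_len(n)) {
        x0 <- 30 + (i - 1) * (bar_w + gap)
        tot <- kt$total_mean[i] * scale
        sht <- kt$short_mean[i] * scale
        ln <- c(ln, sprintf(
            '<rect x="%.1f" y="%.1f" width="%d" height="%.1f" rx="8" fill="none" stroke="black"/>',
            x0, top, bar_w, tot))
        if (!is.null(idiogram$annotations)) {
            an <- idiogram$annotations[
                idiogram$annotations$chrom == kt$chrom_label[i], ,
                drop = FALSE]
            for (j in seq_len(nrow(an))) {
                ext <- region_extent(an$region[j], sht, tot)
                ln <- c(ln, sprintf(
                    '<rect x="%.1f" y="%.1f" width="%d" height="%.1f" fill="%s" fill-opacity="0.7"/>',
                    x0, top + ext[1], bar_w, ext[2] - ext[1], an$color[j]))
            }
        }
        # centromere marker at the short/long arm boundary
        ln <- c(ln, sprintf(
            '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="black" stroke-width="4"/>',
            x0 - 3, top + sht, x0 + bar_w + 3, top + sht))
        ln <- c(ln, sprintf(
            '<text x="%.1f" y="%.1f" font-size="12" text-anchor="middle">%s</text>',
            x0 + bar_w / 2, top + max_h + 20, kt$chrom_label[i]))
        ln <- c(ln, sprintf(
            '<text x="%.1f" y="%.1f" font-size="10" text-anchor="middle">%.2f um</text>',
            x0 + bar_w / 2, top + max_h + 36,
            round_half_up(kt$total_mean[i], 2)))
    }
    ln <- c(ln, "</svg>")
    writeLines(ln, path)
    invisible(path)
}

#' Export an idiogram as JSON
#'
#' @param idiogram an [build_idiogram()] object.
#' @param path output JSON file.
#' @export
write_idiogram_json <- function(idiogram, path) {
    stopifnot(inherits(idiogram, "idiogram"))
    kt <- idiogram$karyotype
    kt <- kt[natural_order(kt$chrom_label), , drop = FALSE]
    num <- vapply(kt, is.numeric, logical(1))
    kt[num] <- lapply(kt[num], function(v) round_half_up(v, 2))
    jsonlite::write_json(
        list(chromosomes = kt,
             annotations = if (is.null(idiogram$annotations))
                 list() else idiogram$annotations),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}
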