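#' Sequential-FISH planning constraints
#'
#' Two fluorophore channels per round by default (digoxigenin/red and
#' biotin/green).  Extra probes are single-locus probes with a known
#' target chromosome (for example 5S and 35S rDNA); they co-hybridize
#' with a painting probe sharing a channel and therefore do not consume
#' round capacity.  Painting probes are never reused across rounds
#' because sequential re-probing strips the prior signal.
#'
#' @param fluorophores_per_round painting probes per round.
#' @param max_rounds maximum sequential rounds.
#' @param allow_exclusion permit identifying at most one chromosome as the
#'   single leftover after all others are positively identified.
#' @param allow_pattern_disambiguation permit separating chromosomes with
#'   identical binary barcodes by their along-chromosome signal patterns.
#' @param extra_probes named character vector, probe name -> chromosome
#'   label (e.g. `c("5S" = "Sorghum5")`).
#' @param min_level signal level treated as a lit barcode bit:
#'   `"uncertain"` (candidate counts and above) or `"present"`
#'   (confident counts only, i.e. signals expected to be observed).
#' @param tv_threshold total-variation distance (on patterns rescaled to a
#'   common relative-position grid) above which two patterns are called
#'   visually distinct.
#' @return A list of class `plan_constraints`.
#' @export
plan_constraints <- function(fluorophores_per_round = 2L, max_rounds = 5L,
                             allow_exclusion = TRUE,
                             allow_pattern_disambiguation = TRUE,
                             extra_probes = NULL,
                             min_level = c("uncertain", "present"),
                             tv_threshold = 0.2) {
    min_level <- match.arg(min_level)
    if (!is_count(fluorophores_per_round) || fluorophores_per_round < 1)
        stopf("fluorophores_per_round must be >= 1")
    if (!is_count(max_rounds) || max_rounds < 1)
        stopf("max_rounds must be >= 1")
    if (!is.null(extra_probes) &&
        (is.null(names(extra_probes)) || any(names(extra_probes) == "")))
        stopf("extra_probes must be a named character vector")
    structure(list(fluorophores_per_round = as.integer(fluorophores_per_round),
                   max_rounds = as.integer(max_rounds),
                   allow_exclusion = isTRUE(allow_exclusion),
                   allow_pattern_disambiguation =
                       isTRUE(allow_pattern_disambiguation),
                   extra_probes = extra_probes,
                   min_level = min_level,
                   tv_threshold = tv_threshold),
              class = "plan_constraints")
}

#' Construct a sequential-FISH panel plan
#'
#' @param rounds list of character vectors, one per round, naming the
#'   probes hybridized in that round.
#' @return An object of class `fish_panel_plan`.
#' @export
fish_panel_plan <- function(rounds) {
    stopifnot(is.list(rounds))
    rounds <- lapply(rounds, as.character)
    probes <- unlist(rounds)
    if (anyDuplicated(probes))
        stopf("probe '%s' is reused across rounds",
              probes[duplicated(probes)][1])
    structure(list(rounds = rounds, probes = probes, id_map = NULL,
                   resolved = NA), class = "fish_panel_plan")
}

#' @export
print.fish_panel_plan <- function(x, ...) {
    cat(sprintf("sequential FISH plan: %d round(s), %d probe(s)%s\n",
                length(x$rounds), length(x$probes),
                if (isTRUE(x$resolved)) ", resolves all chromosomes"
                else if (isFALSE(x$resolved)) ", NOT fully resolving"
                else ""))
    flu <- c("red", "green")
    for (i in seq_along(x$rounds)) {
        pr <- x$rounds[[i]]
        lab <- paste(sprintf("%s (%s)", pr,
                             flu[pmin(seq_along(pr), length(flu))]),
                     collapse = ", ")
        cat(sprintf("  round %d: %s\n", i, lab))
    }
    if (!is.null(x$id_map)) {
        cat("identification:\n")
        for (cn in names(x$id_map))
            cat(sprintf("  %s: %s\n", cn, x$id_map[[cn]]))
    }
    invisible(x)
}

# rescale a normalized window-pattern vector onto `nbins` relative-position
# bins so chromosomes with different window counts are comparable
rebin_pattern <- function(p, nbins = 20L) {
    n <- length(p)
    out <- numeric(nbins)
    for (i in seq_len(n)) {
        lo <- (i - 1) / n
        hi <- i / n
        bins <- seq(floor(lo * nbins) + 1, min(nbins, ceiling(hi * nbins)))
        for (b in bins) {
            blo <- (b - 1) / nbins
            bhi <- b / nbins
            ov <- max(0, min(hi, bhi) - max(lo, blo))
            out[b] <- out[b] + p[i] * (ov / (hi - lo))
        }
    }
    out
}

# total-variation distance between two normalized patterns
pattern_tv <- function(p, q, nbins = 20L) {
    0.5 * sum(abs(rebin_pattern(p, nbins) - rebin_pattern(q, nbins)))
}

# core resolution logic shared by verify_plan / plan_rounds /
# enumerate_optimal: which chromosomes does this probe set identify?
resolve_chromosomes <- function(calls, probes, constraints) {
    chroms <- colnames(calls$levels)
    if (length(probes) == 0) {
        un <- chroms
        if (constraints$allow_exclusion && length(un) == 1)
            return(list(resolved = setNames("by exclusion", un),
                        unresolved = character(0)))
        return(list(resolved = setNames(character(0), character(0)),
                    unresolved = un))
    }
    B <- barcode_matrix(calls, probes, constraints$min_level,
                        constraints$extra_probes)
    key <- apply(B, 1, paste, collapse = "")
    zero_key <- paste(rep("0", ncol(B)), collapse = "")
    id_map <- setNames(rep(NA_character_, length(chroms)), chroms)
    for (k in unique(key)) {
        members <- chroms[key == k]
        if (k == zero_key) next  # dark chromosomes: exclusion only
        if (length(members) == 1) {
            id_map[members] <- sprintf("barcode %s", k)
        } else if (constraints$allow_pattern_disambiguation) {
            # distinguishable if every pair differs on some shared lit
            # probe's along-chromosome pattern
            pairs_ok <- function(a, b) {
                for (p in probes) {
                    if (B[a, p] == 1 && B[b, p] == 1) {
                        pa <- calls$patterns[[p]][[a]]
                        pb <- calls$patterns[[p]][[b]]
                        if (!is.null(pa) && !is.null(pb) &&
                            pattern_tv(pa, pb) > constraints$tv_threshold)
                            return(TRUE)
                    }
                }
                FALSE
            }
            for (a in members) {
                if (all(vapply(setdiff(members, a),
                               function(b) pairs_ok(a, b), logical(1))))
                    id_map[a] <- sprintf("barcode %s + pattern", k)
            }
        }
    }
    un <- chroms[is.na(id_map)]
    if (constraints$allow_exclusion && length(un) == 1) {
        id_map[un] <- "by exclusion"
        un <- character(0)
    }
    list(resolved = id_map[!is.na(id_map)], unresolved = un)
}

#' Verify a sequential-FISH plan against signal calls
#'
#' A chromosome is resolved when its binary barcode over the planned
#' probes is unique and non-zero, when it is separable from barcode-equal
#' chromosomes by along-chromosome signal patterns (if enabled), or when
#' it is the single leftover under identification-by-exclusion (if
#' enabled).
#'
#' @param plan a [fish_panel_plan()].
#' @param calls a `signal_call`.
#' @param constraints [plan_constraints()].
#' @return List with `resolved` (logical), `unresolved` (chromosome
#'   labels), `id_map` (named evidence strings), `n_rounds`.
#' @export
verify_plan <- function(plan, calls, constraints = plan_constraints()) {
    stopifnot(inherits(plan, "fish_panel_plan"),
              inherits(calls, "signal_call"),
              inherits(constraints, "plan_constraints"))
    extra <- names(constraints$extra_probes)
    for (i in seq_along(plan$rounds)) {
        painting <- setdiff(plan$rounds[[i]], extra)
        if (length(painting) > constraints$fluorophores_per_round)
            stopf("round %d carries %d painting probes; limit is %d",
                  i, length(painting), constraints$fluorophores_per_round)
    }
    missing <- setdiff(plan$probes, c(rownames(calls$levels), extra))
    if (length(missing))
        stopf("probe '%s' is neither in the signal calls nor an extra probe",
              missing[1])
    res <- resolve_chromosomes(calls, plan$probes, constraints)
    list(resolved = length(res$unresolved) == 0,
         unresolved = res$unresolved,
         id_map = as.list(res$resolved),
         n_rounds = length(plan$rounds))
}

#' Greedily plan sequential-FISH rounds
#'
#' Repeatedly adds the probe that newly resolves the most chromosomes
#' (ties: fewer candidate chromosomes, then label order), continuing while
#' unresolved chromosomes and round capacity remain even through
#' zero-gain picks (two probes can jointly split a group neither splits
#' alone).  Chosen painting probes are packed into rounds in selection
#' order, `fluorophores_per_round` per round; extra single-locus probes
#' ride along on the last round.
#'
#' @param calls a `signal_call`.
#' @param constraints [plan_constraints()].
#' @return A [fish_panel_plan()] with `resolved` and `id_map` filled in;
#'   `resolved = FALSE` marks the best partial plan.
#' @export
plan_rounds <- function(calls, constraints = plan_constraints()) {
    stopifnot(inherits(calls, "signal_call"),
              inherits(constraints, "plan_constraints"))
    pool <- rownames(calls$levels)
    extra <- names(constraints$extra_probes)
    if (length(pool) + length(extra) == 0) stopf("no probes available")
    budget <- constraints$max_rounds * constraints$fluorophores_per_round
    # candidate-set size per probe, for tie-breaking
    lit_count <- function(p) {
        B <- barcode_matrix(calls, p, constraints$min_level,
                            constraints$extra_probes)
        sum(B)
    }
    chosen <- character(0)
    n_painting <- 0L
    best <- resolve_chromosomes(calls, chosen, constraints)
    repeat {
        if (length(best$unresolved) == 0) break
        avail <- setdiff(c(pool, extra), chosen)
        if (n_painting >= budget) avail <- intersect(avail, extra)
        if (length(avail) == 0) break
        gain <- vapply(avail, function(p) {
            r <- resolve_chromosomes(calls, c(chosen, p), constraints)
            length(r$resolved)
        }, integer(1))
        lit <- vapply(avail, lit_count, integer(1))
        ord <- order(-gain, lit, avail)
        pick <- avail[ord[1]]
        chosen <- c(chosen, pick)
        if (!pick %in% extra) n_painting <- n_painting + 1L
        best <- resolve_chromosomes(calls, chosen, constraints)
    }
    painting <- setdiff(chosen, extra)
    k <- constraints$fluorophores_per_round
    rounds <- if (length(painting)) {
        split(painting, (seq_along(painting) - 1L) %/% k)
    } else list()
    rounds <- unname(lapply(rounds, as.character))
    extras_used <- intersect(chosen, extra)
    if (length(extras_used)) {
        if (length(rounds) == 0) rounds <- list(character(0))
        rounds[[length(rounds)]] <- c(rounds[[length(rounds)]], extras_used)
    }
    plan <- fish_panel_plan(rounds)
    plan$id_map <- as.list(best$resolved)
    plan$resolved <- length(best$unresolved) == 0
    plan$unresolved <- best$unresolved
    plan
}

#' Exhaustively enumerate minimum resolving probe subsets
#'
#' Brute-force oracle over all probe subsets by increasing size, returning
#' every minimum-size subset that resolves all chromosomes under the
#' constraints.  Guarded to small instances.
#'
#' @param calls a `signal_call`.
#' @param constraints [plan_constraints()].
#' @param max_probes largest subset size to try.
#' @return List of character vectors (each a minimum resolving subset);
#'   empty when none resolves within `max_probes`.
#' @export
enumerate_optimal <- function(calls, constraints = plan_constraints(),
                              max_probes = NULL) {
    stopifnot(inherits(calls, "signal_call"),
              inherits(constraints, "plan_constraints"))
    pool <- c(rownames(calls$levels), names(constraints$extra_probes))
    if (length(pool) > 12) stopf("enumeration limited to <= 12 probes")
    if (ncol(calls$levels) > 12)
        stopf("enumeration limited to <= 12 chromosomes")
    if (length(pool) == 0) return(list())
    if (is.null(max_probes)) max_probes <- length(pool)
    max_probes <- min(max_probes, length(pool))
    for (s in seq_len(max_probes)) {
        subs <- combn(pool, s, simplify = FALSE)
        ok <- Filter(function(p) {
            length(resolve_chromosomes(calls, p, constraints)$unresolved) == 0
        }, subs)
        if (length(ok)) return(ok)
    }
    list()
}
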