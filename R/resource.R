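#' Construct a ligand-receptor resource
#'
#' Builds an [LRResource-class] from entity strings, canonicalising complexes
#' and dropping duplicate (transmitter, receiver) identities within each
#' resource label.
#'
#' @param source,target character vectors of transmitter / receiver entity
#'   strings (complex subunits joined by \code{"_"})
#' @param resource resource provenance label(s), recycled
#' @param category optional semicolon-separated category labels, recycled
#' @param curation_effort optional non-negative integer literature-reference
#'   counts, recycled
#' @return an \code{LRResource}
#' @examples
#' lrResource(c("TGFB1", "IL6"), c("TGFBR1_TGFBR2", "IL6R_IL6ST"))
#' @export
lrResource <- function(source, target, resource = "resource",
                       category = NULL, curation_effort = NULL) {
    stopifnot(length(source) == length(target))
    tab <- data.frame(
        source_genesymbol = .canonVec(as.character(source)),
        target_genesymbol = .canonVec(as.character(target)),
        resource = rep_len(as.character(resource), length(source)),
        stringsAsFactors = FALSE)
    if (!is.null(category))
        tab$category <- rep_len(as.character(category), nrow(tab))
    if (!is.null(curation_effort))
        tab$curation_effort <- rep_len(as.integer(curation_effort), nrow(tab))
    id <- paste(tab$resource, tab$source_genesymbol, tab$target_genesymbol,
                sep = "\r")
    tab <- tab[!duplicated(id), , drop = FALSE]
    rownames(tab) <- NULL
    new("LRResource", interactions = tab)
}

#' Read a ligand-receptor resource from CSV
#'
#' Expects columns \code{source_genesymbol} and \code{target_genesymbol}
#' (subunits joined by \code{"_"}); optional \code{resource},
#' \code{category} and \code{curation_effort} columns are carried through.
#'
#' @param path path to a CSV file
#' @return an [LRResource-class]
#' @export
readLRResource <- function(path) {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("source_genesymbol", "target_genesymbol")
    if (!all(need %in% colnames(tab)))
        stop("resource CSV must have columns source_genesymbol, target_genesymbol")
    lrResource(tab$source_genesymbol, tab$target_genesymbol,
               resource = if ("resource" %in% colnames(tab)) tab$resource
                          else "resource",
               category = if ("category" %in% colnames(tab)) tab$category,
               curation_effort = if ("curation_effort" %in% colnames(tab))
                   tab$curation_effort)
}

#' Write a resource table to CSV
#' @param x an [LRResource-class]
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeLRResource <- function(x, path) {
    stopifnot(is(x, "LRResource"))
    write.csv2 <- function(...) utils::write.csv(..., row.names = FALSE)
    write.csv2(x@interactions, path)
    invisible(path)
}

#' Dissociate heteromeric complexes into subunit pairs
#'
#' Every complex-containing record is expanded into all transmitter-subunit x
#' receiver-subunit combinations, then de-duplicated, so that all records are
#' single-gene interactions. Idempotent.
#'
#' @param x an [LRResource-class]
#' @return an \code{LRResource} with single-subunit records only
#' @examples
#' r <- lrResource("A_B", "C_D")
#' length(dissociateComplexes(r))  # 4
#' @export
dissociateComplexes <- function(x) {
    stopifnot(is(x, "LRResource"))
    tab <- x@interactions
    if (nrow(tab) == 0L) return(x)
    pieces <- lapply(seq_len(nrow(tab)), function(i) {
        su <- entitySubunits(tab$source_genesymbol[i])
        tu <- entitySubunits(tab$target_genesymbol[i])
        grid <- expand.grid(source_genesymbol = su, target_genesymbol = tu,
                            stringsAsFactors = FALSE)
        grid$resource <- tab$resource[i]
        if ("category" %in% colnames(tab)) grid$category <- tab$category[i]
        if ("curation_effort" %in% colnames(tab))
            grid$curation_effort <- tab$curation_effort[i]
        grid
    })
    out <- do.call(rbind, pieces)
    id <- paste(out$resource, out$source_genesymbol, out$target_genesymbol,
                sep = "\r")
    out <- out[!duplicated(id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "out.attrs") <- NULL
    new("LRResource", interactions = out)
}

#' Read a gene annotation table
#'
#' Maps gene symbols to category labels, optionally with a consensus
#' localisation percentile in \[0, 100\]. CSV columns: \code{genesymbol},
#' \code{category}, optional \code{consensus_percentile}. A gene may appear
#' on several rows (multi-category matching is allowed).
#'
#' @param path CSV path, or a \code{data.frame} with the same columns
#' @return a \code{data.frame} with upper-cased \code{genesymbol}
#' @export
readAnnotations <- function(path) {
    tab <- if (is.data.frame(path)) path else read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("genesymbol", "category") %in% colnames(tab)))
        stop("annotation table needs columns genesymbol, category")
    tab$genesymbol <- toupper(trimws(tab$genesymbol))
    if (!all(nzchar(tab$category))) stop("empty category labels")
    if ("consensus_percentile" %in% colnames(tab) &&
        any(tab$consensus_percentile < 0 | tab$consensus_percentile > 100,
            na.rm = TRUE))
        stop("consensus_percentile outside [0,100]")
    tab
}

#' Filter interactions by receiver membrane localisation
#'
#' Keeps records whose receiver subunits all carry a qualifying localisation
#' category with a consensus percentile at or above the threshold; genes
#' absent from the annotation table fail the filter. Mirrors restricting a
#' composite resource to interactions whose receiver is plasma-membrane
#' transmembrane or peripheral at the 51st consensus percentile.
#'
#' @param x an [LRResource-class]
#' @param annotations annotation table (see [readAnnotations()]) with
#'   \code{consensus_percentile}
#' @param categories character, the qualifying localisation categories
#' @param percentile_threshold numeric, default 51
#' @return filtered \code{LRResource}
#' @export
filterByLocalisation <- function(x, annotations,
                                 categories = c("plasma membrane transmembrane",
                                                "plasma membrane peripheral"),
                                 percentile_threshold = 51) {
    stopifnot(is(x, "LRResource"))
    ann <- readAnnotations(annotations)
    if (!"consensus_percentile" %in% colnames(ann))
        stop("annotations lack consensus_percentile")
    ok_genes <- unique(ann$genesymbol[ann$category %in% categories &
                                      ann$consensus_percentile >= percentile_threshold])
    keep <- vapply(x@interactions$target_genesymbol, function(ent)
        all(entitySubunits(ent) %in% ok_genes), NA)
    out <- x@interactions[keep, , drop = FALSE]
    rownames(out) <- NULL
    new("LRResource", interactions = out)
}

#' Filter interactions by curation support
#'
#' Keeps records with \code{curation_effort} above (or at) a minimum count of
#' literature references.
#'
#' @param x an [LRResource-class] with a \code{curation_effort} column
#' @param min_refs minimum reference count; default keeps records with
#'   \code{curation_effort > 0}
#' @param inclusive if \code{TRUE}, keep \code{>= min_refs} instead of
#'   \code{> min_refs - 1}; with the defaults both mean "at least one"
#' @return filtered \code{LRResource}
#' @export
filterByCuration <- function(x, min_refs = 1L, inclusive = TRUE) {
    stopifnot(is(x, "LRResource"))
    if (!"curation_effort" %in% colnames(x@interactions))
        stop("resource has no curation_effort column")
    ce <- x@interactions$curation_effort
    keep <- if (inclusive) ce >= min_refs else ce > min_refs
    keep[is.na(keep)] <- FALSE
    out <- x@interactions[keep, , drop = FALSE]
    rownames(out) <- NULL
    new("LRResource", interactions = out)
}

# elements of one resource for a given component, after dissociation
.resourceElements <- function(tab, component) {
    switch(component,
        interaction = unique(paste(tab$source_genesymbol,
                                   tab$target_genesymbol, sep = "^")),
        transmitter = unique(tab$source_genesymbol),
        receiver = unique(tab$target_genesymbol),
        stop("unknown component: ", component))
}

.splitByResource <- function(x) {
    tab <- dissociateComplexes(x)@interactions
    split(tab, tab$resource)
}

#' Unique vs shared elements across resources
#'
#' For each resource in a multi-resource collection, counts elements
#' (interactions, transmitters or receivers, after complex dissociation)
#' found in no other resource (unique) versus in at least one other (shared).
#'
#' @param x an [LRResource-class] holding >= 2 resource labels
#' @param component one of \code{"interaction"}, \code{"transmitter"},
#'   \code{"receiver"}
#' @return \code{data.frame(resource, n_unique, n_shared, pct_unique)};
#'   \code{pct_unique} in percent
#' @export
overlapStats <- function(x, component = c("interaction", "transmitter",
                                          "receiver")) {
    component <- match.arg(component)
    parts <- .splitByResource(x)
    if (length(parts) < 2L) stop("overlapStats needs >= 2 resources")
    sets <- lapply(parts, .resourceElements, component = component)
    all_el <- unlist(sets, use.names = FALSE)
    n_res_of <- table(unlist(lapply(sets, unique), use.names = FALSE))
    out <- do.call(rbind, lapply(names(sets), function(r) {
        el <- sets[[r]]
        uniq <- sum(n_res_of[el] == 1L)
        data.frame(resource = r, n_unique = uniq,
                   n_shared = length(el) - uniq,
                   pct_unique = 100 * uniq / length(el),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Pairwise similarity between resources
#'
#' Jaccard index (symmetric, unit diagonal) and asymmetric containment,
#' where \code{containment[A, B]} is the fraction of B's elements present in
#' A. Computed after complex dissociation.
#'
#' @inheritParams overlapStats
#' @return list with matrices \code{jaccard} and \code{containment}; empty
#'   resources yield similarity 0 against non-empty sets with a warning
#' @export
pairwiseSimilarity <- function(x, component = c("interaction", "transmitter",
                                                "receiver")) {
    component <- match.arg(component)
    parts <- .splitByResource(x)
    if (length(parts) < 2L) stop("pairwiseSimilarity needs >= 2 resources")
    sets <- lapply(parts, .resourceElements, component = component)
    if (any(lengths(sets) == 0L))
        warning("empty resource; similarity against it set to 0")
    nms <- names(sets)
    n <- length(sets)
    jac <- matrix(0, n, n, dimnames = list(nms, nms))
    con <- matrix(0, n, n, dimnames = list(nms, nms))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        a <- sets[[i]]; b <- sets[[j]]
        inter <- length(intersect(a, b))
        uni <- length(union(a, b))
        jac[i, j] <- if (uni == 0L) 0 else inter / uni
        con[i, j] <- if (length(b) == 0L) 0 else inter / length(b)
    }
    diag(jac) <- 1
    list(jaccard = jac, containment = con)
}

#' Sample odds ratio of a 2x2 table with Haldane correction
#'
#' Point estimate \code{(a d)/(b c)}; when any cell is zero, 0.5 is added to
#' all four cells for the estimate. The p-value, where needed, is computed by
#' the exact test on the raw counts.
#'
#' @param tab 2x2 numeric matrix or length-4 vector (a, b, c, d)
#' @return numeric odds ratio
#' @export
sampleOddsRatio <- function(tab) {
    x <- as.numeric(tab)
    stopifnot(length(x) == 4L, all(x >= 0))
    if (any(x == 0)) x <- x + 0.5
    (x[1] * x[4]) / (x[2] * x[3])
}

#' Category enrichment of resources against the collection
#'
#' Fisher's exact test comparing, for each annotation category, the category
#' split of one resource's elements against the split in the union of all
#' resources (the background universe, which includes the resource itself,
#' so a resource matching the collection is unenriched). In
#' \code{"interaction"} mode a record matches a category only when both the
#' transmitter and the receiver are matched to that same category;
#' transmitters and receivers are tested independently in the other modes.
#' Multi-category matching is allowed. p-values are Benjamini-Hochberg
#' corrected across all resource x category tests, and a significance flag is
#' assigned when \code{|log2(OR)| > 1} and the FDR reaches the tier.
#'
#' @param x an [LRResource-class] with >= 2 resources
#' @param annotations annotation table (see [readAnnotations()])
#' @param mode one of \code{"interaction"}, \code{"transmitter"},
#'   \code{"receiver"}
#' @return \code{data.frame(resource, category, n_in, n_out, bg_in, bg_out,
#'   odds_ratio, p, fdr, flag)}; \code{flag} one of \code{"none"},
#'   \code{"0.05"}, \code{"0.01"}, \code{"0.001"}
#' @export
categoryEnrichment <- function(x, annotations,
                               mode = c("interaction", "transmitter",
                                        "receiver")) {
    mode <- match.arg(mode)
    ann <- readAnnotations(annotations)
    cat_of <- split(ann$category, ann$genesymbol)
    parts <- .splitByResource(x)
    if (length(parts) < 2L) stop("categoryEnrichment needs >= 2 resources")
    component <- if (mode == "interaction") "interaction" else mode
    sets <- lapply(parts, .resourceElements, component = component)
    bg <- unique(unlist(sets, use.names = FALSE))
    cats_of_element <- function(el) {
        if (mode == "interaction") {
            gg <- strsplit(el, "^", fixed = TRUE)[[1]]
            intersect(cat_of[[gg[1]]], cat_of[[gg[2]]])
        } else unique(cat_of[[el]])
    }
    bg_cats <- lapply(bg, cats_of_element)
    names(bg_cats) <- bg
    all_cats <- sort(unique(unlist(bg_cats, use.names = FALSE)))
    if (length(all_cats) == 0L)
        return(data.frame(resource = character(), category = character(),
                          n_in = integer(), n_out = integer(),
                          bg_in = integer(), bg_out = integer(),
                          odds_ratio = numeric(), p = numeric(),
                          fdr = numeric(), flag = character()))
    rows <- list()
    for (r in names(sets)) {
        el <- sets[[r]]
        in_res <- bg %in% el
        for (cc in all_cats) {
            in_cat <- vapply(bg_cats, function(v) cc %in% v, NA)
            # resource column vs the full collection column (the background
            # includes the resource itself, so an all-encompassing resource
            # has odds ratio exactly 1)
            a <- sum(in_res & in_cat); b <- sum(in_res & !in_cat)
            c_ <- sum(in_cat); d <- sum(!in_cat)
            tab <- matrix(c(a, c_, b, d), 2)
            rows[[length(rows) + 1L]] <- data.frame(
                resource = r, category = cc, n_in = a, n_out = b,
                bg_in = c_, bg_out = d,
                odds_ratio = sampleOddsRatio(c(a, b, c_, d)),
                p = fisher.test(tab)$p.value, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out$fdr <- p.adjust(out$p, method = "BH")
    big <- abs(log2(out$odds_ratio)) > 1
    out$flag <- "none"
    out$flag[big & out$fdr <= 0.05] <- "0.05"
    out$flag[big & out$fdr <= 0.01] <- "0.01"
    out$flag[big & out$fdr <= 0.001] <- "0.001"
    rownames(out) <- NULL
    out
}
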