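## Combinatorial immunolabeling classification of germ cells and
## construction of compositional substage frequency tables.

#' Marker vocabularies and the substage classification criteria
#'
#' Four marker proteins discriminate spermatogonia and seven meiotic
#' prophase substages on spread chromatin: SYCP3 (synaptonemal-complex axis
#' morphology), gamma-H2AX (double-strand-break chromatin signal, restricted
#' to the XY body from pachynema on), STRA8 (meiosis-initiation factor in
#' differentiating spermatogonia and early spermatocytes) and the testis
#' histone variant H1T (positive from mid-pachynema). Each of the eight cell
#' classes has a unique combination of marker states; the vocabularies are
#' closed. Note "weakly_positive" STRA8 is a distinct level (it is what
#' separates late leptonema), not a synonym of "positive".
#'
#' @return `markerCriteria()` returns a data.frame with columns `substage`,
#'   `sycp3`, `gh2ax`, `stra8`, `h1t`: one row per class, in developmental
#'   order. `substageLabels()` returns the 8 class labels in developmental
#'   order. `markerLevels()` returns a named list of the allowed levels per
#'   marker.
#' @examples
#' markerCriteria()
#' @export
markerCriteria <- function() {
    data.frame(
        substage = substageLabels(),
        sycp3 = c("none", "patches", "patches", "fine_foci",
                  "partially_paired", "paired", "paired",
                  "partially_dissociated"),
        gh2ax = c("negative", "negative", "positive", "positive",
                  "patches", "xy_restricted", "xy_restricted",
                  "xy_restricted"),
        stra8 = c("positive", "positive", "positive", "weakly_positive",
                  "negative", "negative", "negative", "negative"),
        h1t = c("negative", "negative", "negative", "negative",
                "negative", "negative", "positive", "positive"),
        stringsAsFactors = FALSE)
}

#' @rdname markerCriteria
#' @export
substageLabels <- function() {
    c("Spermatogonia", "Preleptonema", "EarlyLeptonema", "LateLeptonema",
      "Zygonema", "EarlyPachynema", "LatePachynema", "Diplonema")
}

#' @rdname markerCriteria
#' @export
markerLevels <- function() {
    list(sycp3 = c("none", "patches", "fine_foci", "partially_paired",
                   "paired", "partially_dissociated"),
         gh2ax = c("negative", "positive", "patches", "xy_restricted"),
         stra8 = c("negative", "weakly_positive", "positive"),
         h1t = c("negative", "positive"))
}

#' Default merging of the 8 scored classes into 6 analysis groups
#'
#' Substages whose frequencies track each other across the developmental
#' time span carry no independent covariance signal, so late leptonema is
#' pooled with zygonema and late pachynema with diplonema before the
#' covariance analysis.
#'
#' @return named character vector mapping each of the 8 scored labels to one
#'   of 6 group labels.
#' @export
defaultMergeMap <- function() {
    c(Spermatogonia = "Spermatogonia",
      Preleptonema = "Preleptonema",
      EarlyLeptonema = "EarlyLeptonema",
      LateLeptonema = "LateLeptonema/Zygonema",
      Zygonema = "LateLeptonema/Zygonema",
      EarlyPachynema = "EarlyPachynema",
      LatePachynema = "LatePachynema/Diplonema",
      Diplonema = "LatePachynema/Diplonema")
}

.checkMarkerLevels <- function(sycp3, gh2ax, stra8, h1t) {
    lv <- markerLevels()
    bad <- c(
        if (any(!sycp3 %in% lv$sycp3)) "sycp3",
        if (any(!gh2ax %in% lv$gh2ax)) "gh2ax",
        if (any(!stra8 %in% lv$stra8)) "stra8",
        if (any(!h1t %in% lv$h1t)) "h1t")
    if (length(bad))
        stop("invalid marker level in field(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
}

#' Classify germ cells from their marker profile
#'
#' Deterministic lookup of the unique cell class matching a combination of
#' SYCP3 / gamma-H2AX / STRA8 / H1T states. Combinations outside the eight
#' scored classes are an error (`"pmca_unmatched_profile"`): only these
#' classes enter the closed composition, so callers wanting leniency should
#' pre-filter.
#'
#' @param sycp3,gh2ax,stra8,h1t character vectors (recycled to a common
#'   length) of marker states; see [markerLevels()].
#' @return character vector of substage labels.
#' @examples
#' classifyCell("none", "negative", "positive", "negative")  # Spermatogonia
#' @export
classifyCell <- function(sycp3, gh2ax, stra8, h1t) {
    n <- max(length(sycp3), length(gh2ax), length(stra8), length(h1t))
    sycp3 <- rep_len(sycp3, n); gh2ax <- rep_len(gh2ax, n)
    stra8 <- rep_len(stra8, n); h1t <- rep_len(h1t, n)
    .checkMarkerLevels(sycp3, gh2ax, stra8, h1t)
    crit <- markerCriteria()
    key <- paste(crit$sycp3, crit$gh2ax, crit$stra8, crit$h1t, sep = "|")
    query <- paste(sycp3, gh2ax, stra8, h1t, sep = "|")
    idx <- match(query, key)
    if (anyNA(idx)) {
        off <- query[which(is.na(idx))[1L]]
        cond <- simpleError(paste0(
            "marker combination not among the eight scored classes: ", off))
        class(cond) <- c("pmca_unmatched_profile", class(cond))
        stop(cond)
    }
    crit$substage[idx]
}

#' Build a compositional substage frequency table from per-cell calls
#'
#' Tallies substage calls per sample and converts counts to proportions of
#' scored cells, so every sample column sums to 1.
#'
#' @param calls data.frame with columns `sample_id` and `substage` (one row
#'   per scored cell), or a named list of character vectors of substage
#'   labels (one element per sample).
#' @param substages character vector fixing row identity and order; defaults
#'   to the 8 scored classes in developmental order.
#' @return a [CytologyTable-class] with counts attached.
#' @examples
#' calls <- data.frame(sample_id = c("a", "a", "b"),
#'                     substage = c("Zygonema", "Diplonema", "Diplonema"))
#' frequencies(frequencyTable(calls))
#' @export
frequencyTable <- function(calls, substages = substageLabels()) {
    if (is.list(calls) && !is.data.frame(calls)) {
        calls <- data.frame(
            sample_id = rep(names(calls), lengths(calls)),
            substage = unlist(calls, use.names = FALSE),
            stringsAsFactors = FALSE)
    }
    stopifnot(is.data.frame(calls),
              all(c("sample_id", "substage") %in% names(calls)))
    if (!nrow(calls))
        stop("no calls supplied", call. = FALSE)
    if (any(!calls$substage %in% substages))
        stop("unknown substage label(s): ",
             paste(unique(setdiff(calls$substage, substages)), collapse = ", "),
             call. = FALSE)
    samples <- unique(as.character(calls$sample_id))
    cnt <- table(factor(calls$substage, levels = substages),
                 factor(calls$sample_id, levels = samples))
    cnt <- matrix(as.integer(cnt), nrow = length(substages),
                  dimnames = list(substages, samples))
    tot <- colSums(cnt)
    if (any(tot == 0))
        stop("sample(s) without calls: ",
             paste(samples[tot == 0], collapse = ", "), call. = FALSE)
    new("CytologyTable", frequencies = sweep(cnt, 2, tot, "/"),
        counts = cnt)
}

#' Construct a CytologyTable from a proportion matrix
#'
#' @param frequencies numeric substage-by-sample matrix of proportions with
#'   dimnames; each column must sum to 1 within 1e-9.
#' @param counts optional integer matrix of scored cells, same shape.
#' @return a [CytologyTable-class].
#' @export
CytologyTable <- function(frequencies, counts = NULL) {
    storage.mode(frequencies) <- "double"
    if (is.null(counts)) counts <- matrix(integer(0), 0, 0)
    new("CytologyTable", frequencies = frequencies, counts = counts)
}

#' Merge substage rows into analysis groups
#'
#' Sums frequency (and count) rows that belong to the same group; column
#' sums are conserved, so the table stays compositional. The default map
#' pools late leptonema with zygonema and late pachynema with diplonema,
#' yielding the 6 groups used by the covariance analysis.
#'
#' @param table a [CytologyTable-class].
#' @param mergeMap named character vector mapping every input substage label
#'   to a group label; see [defaultMergeMap()].
#' @return a [CytologyTable-class] with one row per group, ordered by first
#'   appearance of each group along the input row order.
#' @export
mergeSubstages <- function(table, mergeMap = defaultMergeMap()) {
    stopifnot(is(table, "CytologyTable"))
    f <- frequencies(table)
    unmapped <- setdiff(rownames(f), names(mergeMap))
    if (length(unmapped))
        stop("substage label(s) missing from mergeMap: ",
             paste(unmapped, collapse = ", "), call. = FALSE)
    grp <- unname(mergeMap[rownames(f)])
    groups <- unique(grp)
    agg <- function(m) {
        out <- rowsum(m, group = factor(grp, levels = groups))
        rownames(out) <- groups
        out[groups, , drop = FALSE]
    }
    cnt <- cellCounts(table)
    CytologyTable(agg(f), counts = if (is.null(cnt)) NULL else agg(cnt))
}

#' Read and write cytology tables
#'
#' Tab-separated matrix: first column the substage label, remaining columns
#' one per sample; values are proportions.
#'
#' @param path file path.
#' @return `readCytology` returns a [CytologyTable-class];
#'   `writeCytology` invisibly returns `path`.
#' @export
readCytology <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("cytology file must have a label column and >= 1 sample column",
             call. = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m))
        stop("non-numeric frequency values in ", path, call. = FALSE)
    rownames(m) <- as.character(df[[1L]])
    CytologyTable(m)
}

#' @rdname readCytology
#' @param table a [CytologyTable-class].
#' @export
writeCytology <- function(table, path) {
    f <- frequencies(table)
    df <- data.frame(substage = rownames(f),
                     format(f, digits = 10, trim = TRUE, scientific = FALSE),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read per-cell marker call tables
#'
#' Tab-separated text with header `sample_id, sycp3, gh2ax, stra8, h1t`, one
#' row per scored cell; classifies each cell and returns the calls ready for
#' [frequencyTable()].
#'
#' @param path file path.
#' @return data.frame with columns `sample_id`, `substage`.
#' @export
readCellCalls <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "sycp3", "gh2ax", "stra8", "h1t")
    if (!all(need %in% names(df)))
        stop("cell-call file must have columns: ",
             paste(need, collapse = ", "), call. = FALSE)
    data.frame(sample_id = as.character(df$sample_id),
               substage = classifyCell(df$sycp3, df$gh2ax, df$stra8, df$h1t),
               stringsAsFactors = FALSE)
}
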