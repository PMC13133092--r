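#' @include AllClasses.R
NULL

# canonical per-side annotation columns (prefixed sig_/int_)
.sideColumns <- function(side) {
  ep <- .SURV_ENDPOINTS
  c(paste0(side, "_rho"), paste0(side, "_rho_adj_p"),
    paste0(side, "_tn_direction"), paste0(side, "_tn_wilcoxon_p"),
    as.vector(t(outer(ep, c("direction", "p", "chi2", "significant"),
                      function(e, f) paste0(side, "_", e, "_", f)))),
    paste0(side, "_micro_score"), paste0(side, "_immune_class"))
}

.mandatoryColumns <- function() {
  c("id", "cancer_type", .sideColumns("sig"), .sideColumns("int"))
}

.metadataColumns <- function() {
  c("superfamily", "pathway", "phenotype_layer",
    "omic_layer_sig", "omic_layer_int")
}

# Dataset S1 style headers -> canonical names. The supplementary table's
# exact header is not standardized, so this map covers the documented
# title-case layout; unmapped extra columns are carried through untouched.
.datasetS1Map <- function() {
  ep <- toupper(.SURV_ENDPOINTS)
  side_map <- function(pfx, side) {
    nm <- c("Spearman_Rho", "Rho_Adj_P", "TumorNormal_Direction",
            "Wilcoxon_P",
            as.vector(t(outer(ep, c("Cox_Direction", "P", "LogRank_Chi2",
                                    "Significant"),
                              function(e, f) paste0(e, "_", f)))),
            "Microenvironment_Score", "Immune_Class")
    stats::setNames(.sideColumns(side), paste0(pfx, "_", nm))
  }
  c(stats::setNames(
      c("id", "cancer_type", "superfamily", "pathway", "phenotype_layer",
        "omic_layer_sig", "omic_layer_int"),
      c("Circuitry_ID", "Cancer_Type", "Metabolic_Superfamily",
        "Metabolic_Pathway", "Phenotypic_Layer", "Sig_Omic_Layer",
        "Int_Omic_Layer")),
    side_map("Sig", "sig"), side_map("Int", "int"))
}

.normalizeDirection <- function(x, what, where) {
  x0 <- tolower(trimws(as.character(x)))
  x0[x0 %in% c("ns", "n.s.", "non-significant", "nonsignificant",
               "non_significant", "none")] <- "ns"
  ok <- switch(what,
    tn = c("up", "down", "ns"),
    survival = c("risk", "protective", "ns"))
  bad <- which(!x0 %in% ok & !is.na(x0))
  if (length(bad))
    stop(sprintf("unknown %s direction label '%s' (%s, row %d)",
                 what, x[bad[1]], where, bad[1]), call. = FALSE)
  x0
}

.normalizeImmune <- function(x, where) {
  x0 <- tolower(trimws(as.character(x)))
  x0 <- sub("^immune[-_ ]", "", x0)
  ok <- c("hot", "cold", "excluded", "intermediate")
  bad <- which(!x0 %in% ok & !is.na(x0))
  if (length(bad))
    stop(sprintf("unknown immune class '%s' (%s, row %d)",
                 x[bad[1]], where, bad[1]), call. = FALSE)
  x0
}

.asLogicalFlag <- function(x, col) {
  if (is.logical(x)) return(x)
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x0))
  out[x0 %in% c("true", "t", "yes", "1")] <- TRUE
  out[x0 %in% c("false", "f", "no", "0")] <- FALSE
  if (anyNA(out) && !anyNA(x))
    stop(sprintf("column '%s': unparseable logical value '%s'",
                 col, x[which(is.na(out))[1]]), call. = FALSE)
  out
}

#' Construct a circuitry table from a canonical data.frame
#'
#' Validates the canonical column layout (see [readCircuitryTable()] for the
#' schema), normalizes categorical labels and returns a
#' [CircuitryTable-class]. Missing optional metadata columns are filled with
#' `NA`; missing mandatory columns raise a schema error naming the column.
#'
#' @param data canonical annotation `data.frame`, one row per circuitry.
#' @param dialect dialect label recorded on the object.
#' @param sourcePath provenance path recorded on the object.
#' @return a `CircuitryTable`.
#' @export
CircuitryTable <- function(data, dialect = "generic", sourcePath = "") {
  stopifnot(is.data.frame(data))
  miss <- setdiff(.mandatoryColumns(), names(data))
  if (length(miss))
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (m in setdiff(.metadataColumns(), names(data))) data[[m]] <- NA_character_

  data$id <- as.character(data$id)
  data$cancer_type <- as.character(data$cancer_type)
  for (side in c("sig", "int")) {
    tn <- paste0(side, "_tn_direction")
    data[[tn]] <- .normalizeDirection(data[[tn]], "tn", tn)
    for (e in .SURV_ENDPOINTS) {
      dcol <- paste0(side, "_", e, "_direction")
      scol <- paste0(side, "_", e, "_significant")
      data[[dcol]] <- .normalizeDirection(data[[dcol]], "survival", dcol)
      data[[scol]] <- .asLogicalFlag(data[[scol]], scol)
    }
    im <- paste0(side, "_immune_class")
    data[[im]] <- .normalizeImmune(data[[im]], im)
  }
  numcols <- grep("_(rho|rho_adj_p|tn_wilcoxon_p|p|chi2|micro_score)$",
                  .mandatoryColumns(), value = TRUE)
  for (cn in numcols) {
    v <- data[[cn]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & trimws(as.character(v)) != "")
      if (length(bad))
        stop(sprintf("parse error: unparseable numeric cell at row %d, column '%s'",
                     bad[1], cn), call. = FALSE)
      data[[cn]] <- conv
    }
  }
  rownames(data) <- NULL
  methods::new("CircuitryTable", data = data,
               dialect = dialect, sourcePath = sourcePath)
}

setValidity("CircuitryTable", function(object) {
  d <- object@data
  miss <- setdiff(.mandatoryColumns(), names(d))
  if (length(miss))
    return(paste("missing mandatory column(s):", paste(miss, collapse = ", ")))
  if (nrow(d) == 0) return(TRUE)
  if (anyNA(d$id) || any(!nzchar(d$id)))
    return("circuitry identifiers must be non-empty")
  if (anyDuplicated(d$id))
    return(paste("integrity error: duplicate circuitry id:",
                 d$id[anyDuplicated(d$id)]))
  if (anyNA(d$cancer_type) || any(!nzchar(d$cancer_type)))
    return("cancer-type stratum label required for every circuitry")
  for (side in c("sig", "int")) {
    rho <- d[[paste0(side, "_rho")]]
    if (any(is.finite(rho) & abs(rho) > 1))
      return(paste0(side, "_rho must lie in [-1, 1]"))
    for (pc in paste0(side, c("_rho_adj_p", "_tn_wilcoxon_p"))) {
      p <- d[[pc]]
      if (anyNA(p)) return(paste0("absent cells in mandatory column ", pc))
      if (any(p < 0 | p > 1)) return(paste0(pc, " must lie in [0, 1]"))
    }
    for (e in .SURV_ENDPOINTS) {
      sg <- d[[paste0(side, "_", e, "_significant")]]
      if (anyNA(sg))
        return(paste0("absent significance flags in ", side, "_", e,
                      "_significant"))
      dir <- d[[paste0(side, "_", e, "_direction")]]
      p <- d[[paste0(side, "_", e, "_p")]]
      chi <- d[[paste0(side, "_", e, "_chi2")]]
      need <- which(sg)
      if (any(is.na(dir[need])) || any(is.na(p[need])) || any(is.na(chi[need])))
        return(paste0("significant ", e, " endpoints (", side,
                      ") must carry direction, p and chi2 (absent cells are an error)"))
      if (any(dir[need] == "ns"))
        return(paste0("consistency error: ", side, "_", e,
                      " marked significant with direction 'ns'"))
      if (any(p[need] <= 0 | p[need] > 1))
        return(paste0(side, "_", e, "_p must lie in (0, 1] when significant"))
      if (any(chi[need] < 0))
        return(paste0(side, "_", e, "_chi2 must be non-negative"))
    }
    if (anyNA(d[[paste0(side, "_micro_score")]]))
      return(paste0("absent cells in ", side, "_micro_score"))
    if (anyNA(d[[paste0(side, "_immune_class")]]))
      return(paste0("absent cells in ", side, "_immune_class"))
  }
  TRUE
})

#' Read a circuitry annotation table
#'
#' Reads a TSV/CSV table (delimiter auto-detected from the extension, or set
#' `sep`) with one row per circuitry and both annotation sides, under either
#' the `"generic"` canonical header or the `"dataset_s1"` title-case header
#' (see the README for the column map). Missing optional metadata yields
#' explicit `NA`s; missing mandatory columns, duplicate identifiers and
#' unparseable numeric cells raise errors naming the offending column/row.
#'
#' @param path input file path.
#' @param dialect `"generic"` or `"dataset_s1"`.
#' @param sep field separator; defaults to tab, or comma for `.csv`.
#' @return a [CircuitryTable-class].
#' @examples
#' tab <- simulateAtlas(simulationSpec(nCircuitries = 4, seed = 1))$table
#' tf <- tempfile(fileext = ".tsv")
#' writeCircuitryTable(tab, tf)
#' tab2 <- readCircuitryTable(tf)
#' nCircuitries(tab2)
#' @export
readCircuitryTable <- function(path, dialect = c("generic", "dataset_s1"),
                               sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "",
                           na.strings = c("NA", ""))
  if (dialect == "dataset_s1") {
    map <- .datasetS1Map()
    hit <- names(raw) %in% names(map)
    names(raw)[hit] <- map[names(raw)[hit]]
  }
  tab <- CircuitryTable(raw, dialect = dialect, sourcePath = path)
  methods::validObject(tab)
  tab
}

#' Write a circuitry table
#'
#' Serializes the canonical annotation table as UTF-8 TSV with full numeric
#' precision, so that write-then-read round trips are exact.
#'
#' @param table a [CircuitryTable-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeCircuitryTable <- function(table, path) {
  stopifnot(methods::is(table, "CircuitryTable"))
  .writeFullPrecisionTSV(table@data, path)
  invisible(path)
}

# full-precision TSV writer shared by all table outputs
.writeFullPrecisionTSV <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' @rdname circuitryIds
setMethod("circuitryIds", "CircuitryTable", function(x) x@data$id)

#' @rdname circuitryIds
setMethod("nCircuitries", "CircuitryTable", function(x) nrow(x@data))

#' @rdname circuitryIds
setMethod("circuitryData", "CircuitryTable", function(x) x@data)

#' @rdname circuitryIds
setMethod("tableDialect", "CircuitryTable", function(x) x@dialect)

setMethod("show", "CircuitryTable", function(object) {
  cat("CircuitryTable with", nrow(object@data), "circuitries across",
      length(unique(object@data$cancer_type)), "cancer-type strata\n")
  if (nzchar(object@sourcePath))
    cat("  source:", object@sourcePath, "(dialect:", object@dialect, ")\n")
})
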