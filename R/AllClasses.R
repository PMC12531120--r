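#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom Rcpp sourceCpp
#' @useDynLib fieldcanceR, .registration = TRUE
NULL

## Controlled vocabularies used across the package.
GRADE_LEVELS  <- c("NU", "LGIN", "HGIN", "UC")
GROUP_LEVELS  <- c("NU_LGIN", "HGIN", "UC")
SUB_CLASSES   <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
MTYPE_LEVELS  <- c("SNV", "INS", "DEL")
SPREAD_LEVELS <- c("private", "regional_2_10", "regional_11_20",
                   "widespread_21_30", "widespread_gt30")
GREEK_LEVELS  <- c("alpha", "beta", "gamma")
SHAPE_LEVELS  <- c("right_skewed", "binomial_clonal", "uniform",
                   "indeterminate")

#' Histology grade to analysis group
#'
#' Collapses the four histologic grades into the three analysis groups:
#' normal urothelium and low-grade intraepithelial neoplasia are pooled
#' (NU_LGIN); HGIN and UC stand alone.
#'
#' @param grade character vector of grades (NU, LGIN, HGIN, UC).
#' @return character vector of groups (NU_LGIN, HGIN, UC).
#' @export
#' @examples
#' gradeToGroup(c("NU", "LGIN", "HGIN", "UC"))
gradeToGroup <- function(grade) {
    bad <- setdiff(unique(grade), GRADE_LEVELS)
    if (length(bad))
        stop("unknown grade(s): ", paste(bad, collapse = ", "),
             "; allowed: ", paste(GRADE_LEVELS, collapse = ", "))
    ifelse(grade %in% c("NU", "LGIN"), "NU_LGIN", grade)
}

#' The canonical 96 trinucleotide substitution contexts
#'
#' Substitution-major ordering (C>A, C>G, C>T, T>A, T>C, T>G), then the 5'
#' base A,C,G,T, then the 3' base A,C,G,T, written as e.g. \code{"A[C>T]G"}.
#'
#' @return character vector of length 96.
#' @export
#' @examples
#' head(contexts96())
contexts96 <- function() {
    bases <- c("A", "C", "G", "T")
    unlist(lapply(SUB_CLASSES, function(s)
        as.vector(t(outer(bases, bases, function(p5, p3)
            paste0(p5, "[", s, "]", p3))))))
}

## ---------------------------------------------------------------------------
## FieldMap
## ---------------------------------------------------------------------------

#' FieldMap: spatial grid of mucosal fields
#'
#' Holds the whole-organ sampling grid: one row per mucosal field with its
#' grid coordinates, histologic grade and derived analysis group.
#'
#' @slot map a \code{data.frame} with columns \code{field_id}, \code{row},
#'   \code{col}, \code{grade}, \code{group}.
#' @export
setClass("FieldMap", representation(map = "data.frame"))

setValidity("FieldMap", function(object) {
    m <- object@map
    need <- c("field_id", "row", "col", "grade", "group")
    if (!all(need %in% names(m)))
        return(paste("map must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(m$field_id))
        return("duplicate field_id")
    if (anyDuplicated(paste(m$row, m$col)))
        return("duplicate grid coordinates")
    if (!all(m$grade %in% GRADE_LEVELS))
        return(paste("unknown grade; allowed:",
                     paste(GRADE_LEVELS, collapse = ", ")))
    if (!identical(as.character(m$group), gradeToGroup(m$grade)))
        return("group column inconsistent with grade")
    TRUE
})

#' Construct a FieldMap
#'
#' @param field_id character vector of unique field identifiers.
#' @param row,col integer grid coordinates (unique pairs).
#' @param grade histology grade per field (NU, LGIN, HGIN, UC).
#' @return a \linkS4class{FieldMap}.
#' @export
#' @examples
#' fm <- FieldMap(c("A1", "A2"), row = c(1, 1), col = c(1, 2),
#'                grade = c("NU", "UC"))
#' fieldGroups(fm)
FieldMap <- function(field_id, row, col, grade) {
    m <- data.frame(field_id = as.character(field_id),
                    row = as.integer(row), col = as.integer(col),
                    grade = as.character(grade),
                    group = gradeToGroup(as.character(grade)),
                    stringsAsFactors = FALSE)
    new("FieldMap", map = m)
}

#' @rdname FieldMap-accessors
#' @export
setGeneric("fieldIds", function(x) standardGeneric("fieldIds"))
#' @rdname FieldMap-accessors
#' @export
setGeneric("fieldGrades", function(x) standardGeneric("fieldGrades"))
#' @rdname FieldMap-accessors
#' @export
setGeneric("fieldGroups", function(x) standardGeneric("fieldGroups"))
#' @rdname FieldMap-accessors
#' @export
setGeneric("gridCoords", function(x) standardGeneric("gridCoords"))

#' FieldMap accessors
#'
#' @param x a \linkS4class{FieldMap}.
#' @return \code{fieldIds}: character vector; \code{fieldGrades},
#'   \code{fieldGroups}: named character vectors; \code{gridCoords}: a
#'   data.frame with row/col.
#' @name FieldMap-accessors
NULL

#' @rdname FieldMap-accessors
setMethod("fieldIds", "FieldMap", function(x) x@map$field_id)
#' @rdname FieldMap-accessors
setMethod("fieldGrades", "FieldMap", function(x)
    structure(x@map$grade, names = x@map$field_id))
#' @rdname FieldMap-accessors
setMethod("fieldGroups", "FieldMap", function(x)
    structure(x@map$group, names = x@map$field_id))
#' @rdname FieldMap-accessors
setMethod("gridCoords", "FieldMap", function(x)
    x@map[, c("field_id", "row", "col")])

setMethod("show", "FieldMap", function(object) {
    tab <- table(factor(object@map$grade, GRADE_LEVELS))
    cat("FieldMap with", nrow(object@map), "fields (",
        paste(paste0(names(tab), "=", as.integer(tab)), collapse = ", "),
        ")\n")
})

#' @export
setMethod("length", "FieldMap", function(x) nrow(x@map))

#' Coerce a FieldMap to data.frame
#' @param x a FieldMap.
#' @param ... unused.
#' @return data.frame with field_id, row, col, grade, group.
#' @export
as.data.frame.FieldMap <- function(x, ...) x@map

## ---------------------------------------------------------------------------
## MutationTable
## ---------------------------------------------------------------------------

#' MutationTable: mutations by fields VAF matrix with annotations
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with one assay
#' \code{"vaf"} (mutations in rows, mucosal fields in columns), per-mutation
#' annotations in \code{rowData} (\code{gene}, \code{mtype},
#' \code{substitution}, \code{context}, \code{silent}, optional
#' \code{locus}) and the field map in \code{colData}.
#'
#' @export
setClass("MutationTable", contains = "SummarizedExperiment")

setValidity("MutationTable", function(object) {
    v <- assay(object, "vaf")
    if (any(is.na(v)) || any(v < 0) || any(v > 1))
        return("VAF values must lie in [0, 1] and not be NA")
    rd <- rowData(object)
    need <- c("gene", "mtype", "substitution", "context", "silent")
    if (!all(need %in% names(rd)))
        return(paste("rowData must have", paste(need, collapse = ", ")))
    if (!all(rd$mtype %in% MTYPE_LEVELS))
        return("mtype must be SNV, INS or DEL")
    snv <- rd$mtype == "SNV"
    if (any(snv) && (!all(rd$substitution[snv] %in% SUB_CLASSES) ||
                     !all(rd$context[snv] %in% contexts96())))
        return("every SNV needs a valid substitution class and 96-context")
    if (any(!snv) && (any(!is.na(rd$substitution[!snv])) ||
                      any(!is.na(rd$context[!snv]))))
        return("INS/DEL must have NA substitution and context")
    if (anyDuplicated(rownames(object)))
        return("duplicate mutation ids")
    TRUE
})

#' Construct a MutationTable
#'
#' @param vaf numeric matrix, mutations x fields, values in [0, 1]; column
#'   names must match the field map.
#' @param info data.frame/DataFrame with columns \code{gene}, \code{mtype},
#'   \code{substitution}, \code{context}, \code{silent} (and optionally
#'   \code{locus}); row order matches \code{vaf}.
#' @param fieldMap a \linkS4class{FieldMap}; columns of \code{vaf} are
#'   reordered to its field order.
#' @return a \linkS4class{MutationTable}.
#' @export
MutationTable <- function(vaf, info, fieldMap) {
    ids <- fieldIds(fieldMap)
    if (!setequal(colnames(vaf), ids))
        stop("vaf columns do not match the field map: ",
             paste(symdiff_chr(colnames(vaf), ids), collapse = ", "))
    vaf <- as.matrix(vaf)[, ids, drop = FALSE]
    cd <- DataFrame(as.data.frame(fieldMap))
    rownames(cd) <- ids
    info <- DataFrame(info)
    rownames(info) <- rownames(vaf)
    se <- SummarizedExperiment(assays = list(vaf = vaf),
                               rowData = info, colData = cd)
    new("MutationTable", se)
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))

#' @rdname MutationTable-accessors
#' @export
setGeneric("vafMatrix", function(x) standardGeneric("vafMatrix"))
#' @rdname MutationTable-accessors
#' @export
setGeneric("mutationInfo", function(x) standardGeneric("mutationInfo"))

#' MutationTable accessors
#'
#' @param x a \linkS4class{MutationTable}.
#' @return \code{vafMatrix}: numeric matrix mutations x fields;
#'   \code{mutationInfo}: DataFrame of per-mutation annotations.
#' @name MutationTable-accessors
NULL

#' @rdname MutationTable-accessors
setMethod("vafMatrix", "MutationTable", function(x) assay(x, "vaf"))
#' @rdname MutationTable-accessors
setMethod("mutationInfo", "MutationTable", function(x) rowData(x))

setMethod("show", "MutationTable", function(object) {
    rd <- rowData(object)
    cat("MutationTable:", nrow(object), "mutations x", ncol(object),
        "fields (", sum(rd$mtype == "SNV"), "SNV,",
        sum(rd$mtype == "INS"), "INS,", sum(rd$mtype == "DEL"), "DEL )\n")
})

## ---------------------------------------------------------------------------
## OmicsMatrix
## ---------------------------------------------------------------------------

#' OmicsMatrix: analyte by sample abundance matrix
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with one assay
#' \code{"abundance"} (log-scale; NA allowed for proteomics/metabolomics).
#' \code{colData} carries \code{role} (\code{map_field} or \code{control})
#' and, for map fields, the histology \code{group}.
#'
#' @export
setClass("OmicsMatrix", contains = "SummarizedExperiment")

setValidity("OmicsMatrix", function(object) {
    cd <- colData(object)
    if (!all(c("role", "group") %in% names(cd)))
        return("colData must have role and group")
    if (!all(cd$role %in% c("map_field", "control")))
        return("role must be map_field or control")
    if (!any(cd$role == "control"))
        return("at least one control sample is required")
    if (anyDuplicated(rownames(object)))
        return("duplicate analyte ids")
    TRUE
})

#' Construct an OmicsMatrix
#'
#' @param abundance numeric matrix, analytes x samples (log scale; NA
#'   allowed).
#' @param role character vector per sample: \code{"map_field"} or
#'   \code{"control"}.
#' @param group analysis group per sample (NU_LGIN/HGIN/UC for map fields,
#'   NA for controls). If \code{fieldMap} is given, groups for map-field
#'   samples are taken from it by sample name.
#' @param fieldMap optional \linkS4class{FieldMap}.
#' @return an \linkS4class{OmicsMatrix}.
#' @export
OmicsMatrix <- function(abundance, role, group = NULL, fieldMap = NULL) {
    abundance <- as.matrix(abundance)
    if (is.null(group)) {
        group <- rep(NA_character_, ncol(abundance))
        if (!is.null(fieldMap)) {
            g <- fieldGroups(fieldMap)
            hit <- colnames(abundance) %in% names(g)
            group[hit] <- unname(g[colnames(abundance)[hit]])
        }
    }
    cd <- DataFrame(role = role, group = group)
    rownames(cd) <- colnames(abundance)
    se <- SummarizedExperiment(assays = list(abundance = abundance),
                               colData = cd)
    new("OmicsMatrix", se)
}

#' @rdname OmicsMatrix-accessors
#' @export
setGeneric("abundanceMatrix", function(x) standardGeneric("abundanceMatrix"))
#' @rdname OmicsMatrix-accessors
#' @export
setGeneric("sampleRoles", function(x) standardGeneric("sampleRoles"))
#' @rdname OmicsMatrix-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' OmicsMatrix accessors
#'
#' @param x an \linkS4class{OmicsMatrix}.
#' @return \code{abundanceMatrix}: numeric matrix; \code{sampleRoles},
#'   \code{sampleGroups}: named character vectors.
#' @name OmicsMatrix-accessors
NULL

#' @rdname OmicsMatrix-accessors
setMethod("abundanceMatrix", "OmicsMatrix", function(x)
    assay(x, "abundance"))
#' @rdname OmicsMatrix-accessors
setMethod("sampleRoles", "OmicsMatrix", function(x)
    structure(colData(x)$role, names = colnames(x)))
#' @rdname OmicsMatrix-accessors
setMethod("sampleGroups", "OmicsMatrix", function(x)
    structure(colData(x)$group, names = colnames(x)))

setMethod("show", "OmicsMatrix", function(object) {
    cd <- colData(object)
    cat("OmicsMatrix:", nrow(object), "analytes x", ncol(object),
        "samples (", sum(cd$role == "map_field"), "map fields,",
        sum(cd$role == "control"), "controls );",
        sprintf("%.1f%% missing", 100 * mean(is.na(assay(object)))), "\n")
})

## ---------------------------------------------------------------------------
## SignatureCatalog
## ---------------------------------------------------------------------------

#' SignatureCatalog: 96-context reference signature matrix
#'
#' Columns are reference mutational signatures (probability vectors over the
#' 96 canonical trinucleotide contexts; each column sums to 1). Row order is
#' fixed to \code{\link{contexts96}}.
#'
#' @slot probs numeric 96 x K matrix.
#' @export
setClass("SignatureCatalog", representation(probs = "matrix"))

setValidity("SignatureCatalog", function(object) {
    p <- object@probs
    if (nrow(p) != 96L || !identical(rownames(p), contexts96()))
        return("rows must be the canonical 96 contexts in canonical order")
    if (any(p < 0))
        return("entries must be non-negative")
    cs <- colSums(p)
    if (any(abs(cs - 1) > 1e-6))
        return(paste0("column sums must be 1 +/- 1e-6 (got ",
                      paste(sprintf("%.4f", cs[abs(cs - 1) > 1e-6]),
                            collapse = ", "), ")"))
    if (is.null(colnames(p)) || anyDuplicated(colnames(p)))
        return("signatures need unique column names")
    TRUE
})

#' Construct a SignatureCatalog
#'
#' @param probs numeric matrix with 96 rows (contexts) and one column per
#'   signature; rows may be in any order if rownames are contexts, and are
#'   reordered canonically.
#' @return a \linkS4class{SignatureCatalog}.
#' @export
SignatureCatalog <- function(probs) {
    probs <- as.matrix(probs)
    if (is.null(rownames(probs))) {
        if (nrow(probs) != 96L)
            stop("need 96 context rows")
        rownames(probs) <- contexts96()
    }
    if (!setequal(rownames(probs), contexts96()))
        stop("rownames must be the 96 canonical contexts")
    probs <- probs[contexts96(), , drop = FALSE]
    new("SignatureCatalog", probs = probs)
}

#' @rdname SignatureCatalog-accessors
#' @export
setGeneric("signatureMatrix", function(x) standardGeneric("signatureMatrix"))

#' SignatureCatalog accessors
#' @param x a \linkS4class{SignatureCatalog}.
#' @return \code{signatureMatrix}: the 96 x K probability matrix.
#' @name SignatureCatalog-accessors
NULL

#' @rdname SignatureCatalog-accessors
setMethod("signatureMatrix", "SignatureCatalog", function(x) x@probs)

setMethod("show", "SignatureCatalog", function(object) {
    cat("SignatureCatalog: 96 contexts x", ncol(object@probs),
        "signatures (", paste(colnames(object@probs), collapse = ", "),
        ")\n")
})

#' @export
setMethod("dim", "SignatureCatalog", function(x) dim(x@probs))
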