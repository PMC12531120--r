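## Readers/writers for the package's tab-separated formats. All files are
## UTF-8 TSV with a header row; numbers use a decimal point and are written
## at 6 significant digits, which round-trips bit-exactly.

fmtNum <- function(x, digits = 6) {
    out <- sprintf("%.*g", digits, x)
    out[is.na(x)] <- "NA"
    out
}

readTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "")
}

writeTsv <- function(df, path, digits = 6) {
    num <- vapply(df, is.numeric, logical(1))
    ## integers keep their natural formatting
    num <- num & !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], fmtNum, digits = digits)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    invisible(path)
}

#' Read a field map TSV
#'
#' Expects a header \code{field_id, row, col, grade}.
#'
#' @param path path to a tab-separated file.
#' @return a \linkS4class{FieldMap}.
#' @export
readFieldMap <- function(path) {
    df <- readTsv(path)
    need <- c("field_id", "row", "col", "grade")
    if (!all(need %in% names(df)))
        stop("field map needs columns: ", paste(need, collapse = ", "))
    FieldMap(df$field_id, df$row, df$col, df$grade)
}

#' Write a field map TSV
#' @param fieldMap a \linkS4class{FieldMap}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFieldMap <- function(fieldMap, path) {
    writeTsv(as.data.frame(fieldMap)[c("field_id", "row", "col", "grade")],
             path)
}

#' Parse trinucleotide contexts into substitution classes
#'
#' @param context character vector like \code{"A[C>T]G"}; NA passes through.
#' @return character vector of substitution classes (\code{"C>T"}, ...).
#' @export
#' @examples
#' parseSubstitution("A[C>T]G")
parseSubstitution <- function(context) {
    out <- rep(NA_character_, length(context))
    ok <- !is.na(context)
    sub <- regmatches(context[ok],
                      regexpr("[CT]>[ACGT]", context[ok]))
    if (length(sub) != sum(ok))
        stop("malformed context(s): ",
             paste(utils::head(context[ok][!grepl("\\[[CT]>[ACGT]\\]",
                                                  context[ok])], 3),
                   collapse = ", "))
    out[ok] <- sub
    out
}

#' Read a mutation table TSV
#'
#' One row per mutation with annotation columns \code{mutation_id},
#' \code{gene}, \code{mtype}, \code{context}, \code{silent} (optionally
#' \code{locus} and \code{substitution}) followed by one VAF column per
#' field, named by field id. Missing VAF cells read as 0 (absent). If any
#' VAF exceeds 1 the table is taken to be in percent and divided by 100;
#' the choice is recorded in the \code{"vaf_scale"} attribute (and in run
#' manifests).
#'
#' @param path path to the TSV.
#' @param fieldMap a \linkS4class{FieldMap}; VAF columns are aligned to its
#'   field order.
#' @return a \linkS4class{MutationTable}.
#' @export
readMutationTable <- function(path, fieldMap) {
    df <- readTsv(path)
    anno <- intersect(c("mutation_id", "gene", "mtype", "substitution",
                        "context", "silent", "locus"), names(df))
    if (!all(c("mutation_id", "gene", "mtype", "context") %in% anno))
        stop("mutation table needs mutation_id, gene, mtype, context")
    vafCols <- setdiff(names(df), anno)
    unknown <- setdiff(vafCols, fieldIds(fieldMap))
    if (length(unknown))
        stop("unknown field column(s): ", paste(unknown, collapse = ", "))
    vaf <- as.matrix(df[, vafCols, drop = FALSE])
    storage.mode(vaf) <- "double"
    vaf[is.na(vaf)] <- 0
    scale <- "fraction"
    if (any(vaf > 1)) {
        if (any(vaf > 100))
            stop("VAF values outside [0, 1] (and beyond percent scale)")
        vaf <- vaf / 100
        scale <- "percent"
    }
    if (any(vaf < 0)) stop("negative VAF")
    missing <- setdiff(fieldIds(fieldMap), vafCols)
    if (length(missing)) {
        zero <- matrix(0, nrow(vaf), length(missing),
                       dimnames = list(NULL, missing))
        vaf <- cbind(vaf, zero)
    }
    rownames(vaf) <- df$mutation_id
    ctx <- as.character(df$context)
    ctx[ctx %in% c("", "NA")] <- NA_character_
    snv <- df$mtype == "SNV"
    info <- DataFrame(
        gene = as.character(df$gene),
        mtype = as.character(df$mtype),
        substitution = ifelse(snv, parseSubstitution(ctx), NA_character_),
        context = ifelse(snv, ctx, NA_character_),
        silent = if ("silent" %in% anno) as.logical(df$silent) else FALSE)
    if ("locus" %in% anno) info$locus <- as.character(df$locus)
    rownames(info) <- df$mutation_id
    mt <- MutationTable(vaf, info, fieldMap)
    attr(mt, "vaf_scale") <- scale
    mt
}

#' Write a mutation table TSV
#' @param mut a \linkS4class{MutationTable}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMutationTable <- function(mut, path) {
    rd <- as.data.frame(mutationInfo(mut))
    df <- data.frame(mutation_id = rownames(mut), rd,
                     check.names = FALSE, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(vafMatrix(mut), check.names = FALSE))
    writeTsv(df, path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated
#' \code{name, description, member, member, ...}. Empty sets are retained
#' with a warning.
#'
#' @param path path to the GMT file.
#' @return a named list of character vectors.
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    out <- list()
    for (ln in lines) {
        parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(parts) < 2) stop("malformed GMT line: ", ln)
        members <- unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
        if (!length(members))
            warning("empty gene set: ", parts[1])
        out[[parts[1]]] <- members
    }
    out
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGmt <- function(sets, path) {
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a 96-context signature catalog TSV
#'
#' Expects a \code{context} column plus one numeric column per signature;
#' every signature column must sum to 1 (tolerance 1e-6).
#'
#' @param path path to the TSV.
#' @return a \linkS4class{SignatureCatalog}.
#' @export
readSignatureCatalog <- function(path) {
    df <- readTsv(path)
    if (!"context" %in% names(df))
        stop("signature catalog needs a context column")
    mat <- as.matrix(df[, setdiff(names(df), "context"), drop = FALSE])
    rownames(mat) <- df$context
    SignatureCatalog(mat)
}

#' Write a signature catalog TSV
#' @param catalog a \linkS4class{SignatureCatalog}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSignatureCatalog <- function(catalog, path) {
    m <- signatureMatrix(catalog)
    df <- data.frame(context = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    ## 10 significant digits: column sums must survive the round trip
    writeTsv(df, path, digits = 10)
}

#' Read an omics abundance matrix TSV
#'
#' Analytes in rows (\code{analyte_id} column), samples in columns.
#' Samples listed in \code{controls} get role \code{"control"}; remaining
#' samples are map fields whose histology group is looked up in
#' \code{fieldMap} when given.
#'
#' @param path path to the TSV.
#' @param controls character vector of control sample ids.
#' @param fieldMap optional \linkS4class{FieldMap} for group lookup.
#' @return an \linkS4class{OmicsMatrix}.
#' @export
readOmicsMatrix <- function(path, controls = character(), fieldMap = NULL) {
    df <- readTsv(path)
    if (!"analyte_id" %in% names(df))
        stop("omics matrix needs an analyte_id column")
    mat <- as.matrix(df[, setdiff(names(df), "analyte_id"), drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- df$analyte_id
    role <- ifelse(colnames(mat) %in% controls, "control", "map_field")
    OmicsMatrix(mat, role = role, fieldMap = fieldMap)
}

#' Write an omics abundance matrix TSV
#' @param omics an \linkS4class{OmicsMatrix}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeOmicsMatrix <- function(omics, path) {
    m <- abundanceMatrix(omics)
    df <- data.frame(analyte_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    writeTsv(df, path)
}

#' Write a directory of result tables plus a JSON run manifest
#'
#' Each element of \code{objects} is written as \code{<name>.tsv}
#' (data.frame-like elements) or handled by its own writer (FieldMap,
#' MutationTable, OmicsMatrix, SignatureCatalog). A \code{manifest.json}
#' records parameters, seed, package version and md5 checksums of every
#' file written.
#'
#' @param dir output directory (created if needed).
#' @param objects named list of results.
#' @param params list of run parameters to record.
#' @param seed integer seed to record.
#' @return invisibly, the manifest as a list.
#' @export
writeResults <- function(dir, objects, params = list(), seed = NA) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    for (nm in names(objects)) {
        obj <- objects[[nm]]
        p <- file.path(dir, paste0(nm, ".tsv"))
        if (is(obj, "FieldMap")) writeFieldMap(obj, p)
        else if (is(obj, "MutationTable")) writeMutationTable(obj, p)
        else if (is(obj, "OmicsMatrix")) writeOmicsMatrix(obj, p)
        else if (is(obj, "SignatureCatalog")) writeSignatureCatalog(obj, p)
        else if (inherits(obj, "phylo")) {
            p <- file.path(dir, paste0(nm, ".nwk"))
            ape::write.tree(obj, p)
        } else writeTsv(as.data.frame(obj), p)
        files <- c(files, p)
    }
    manifest <- list(
        package = "fieldcanceR",
        version = as.character(utils::packageVersion("fieldcanceR")),
        seed = seed,
        params = params,
        files = as.list(structure(unname(tools::md5sum(files)),
                                  names = basename(files))))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
}
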