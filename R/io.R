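#' Construct a quantification matrix
#'
#' A `QuantMatrix` is the central container of the pipeline: a protein x
#' sample matrix of log2 intensities with explicit missingness (`NA`).
#' Identifiers live in the dimnames and must be unique; the object carries a
#' `scale` tag so that log2 transformation is applied exactly once at
#' ingestion.
#'
#' @param values numeric matrix, proteins in rows, samples in columns, with
#'   unique non-empty rownames (protein ids) and colnames (sample ids).
#'   Missing quantifications are `NA`.
#' @param scale `"log2"` (the working scale) or `"raw"`. Raw-scale values
#'   are log2-transformed on construction; zeros and negative intensities
#'   become `NA` (they carry no usable abundance information on a log scale).
#' @return an object of class `QuantMatrix`: a list with elements `values`
#'   (numeric matrix, log2 scale) and `scale` (always `"log2"`).
#' @examples
#' m <- matrix(c(8, 4, 2, 16), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' qm <- quant_matrix(m, scale = "raw")
#' qm$values["P1", "s1"]  # log2(8) = 3
#' @export
quant_matrix <- function(values, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  pid <- rownames(values); sid <- colnames(values)
  if ((nrow(values) > 0L && is.null(pid)) ||
      (ncol(values) > 0L && is.null(sid)))
    stop("'values' must have protein rownames and sample colnames")
  if (is.null(pid)) pid <- character()
  if (is.null(sid)) sid <- character()
  dup <- pid[duplicated(pid)]
  if (length(dup)) stop("duplicate protein id: ", dup[[1L]])
  dup <- sid[duplicated(sid)]
  if (length(dup)) stop("duplicate sample id: ", dup[[1L]])
  if (any(is.infinite(values))) stop("'values' contains non-finite entries")
  if (scale == "raw") {
    values[!is.na(values) & values <= 0] <- NA_real_
    values <- log2(values)
  }
  structure(list(values = values, scale = "log2"), class = "QuantMatrix")
}

#' @export
print.QuantMatrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("QuantMatrix: %d proteins x %d samples (log2 scale), %.1f%% missing\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.QuantMatrix <- function(x) dim(x$values)

#' Protein and sample identifiers of a QuantMatrix
#' @param qm a [quant_matrix()]
#' @return character vector of ids, in matrix order.
#' @export
protein_ids <- function(qm) rownames(qm$values)

#' @rdname protein_ids
#' @export
sample_ids <- function(qm) colnames(qm$values)

.sep_for <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  if (dialect == "csv") "," else "\t"
}

# Accepted missing markers; anything else non-numeric is a hard error so a
# malformed cell can never be silently swallowed.
.parse_cells <- function(x, what) {
  miss <- is.na(x) | x == "" | tolower(x) %in% c("na", "nan")
  out <- rep(NA_real_, length(x))
  out[!miss] <- suppressWarnings(as.numeric(x[!miss]))
  bad <- which(!miss & is.na(out))
  if (length(bad))
    stop(sprintf("non-numeric cell in %s: %s", what[bad[[1L]]],
                 x[bad[[1L]]]))
  out
}

#' Read a protein x sample quantification table
#'
#' First column holds protein ids, the header row holds sample ids. Empty
#' cells, `NA` and `NaN` (any case) are missing; any other non-numeric cell
#' is an error naming its position.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @param scale `"log2"` if the file already holds log2 intensities (the
#'   default), `"raw"` for linear-scale intensities. Never guessed from the
#'   data.
#' @return a [quant_matrix()].
#' @export
read_quant_matrix <- function(path, dialect = c("auto", "tsv", "csv"),
                              scale = c("log2", "raw")) {
  sep <- .sep_for(path, match.arg(dialect))
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("quantification table needs >= 1 sample column")
  pid <- df[[1L]]
  vals <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                 dimnames = list(pid, colnames(df)[-1L]))
  for (j in seq_len(ncol(df) - 1L)) {
    col <- df[[j + 1L]]
    vals[, j] <- .parse_cells(
      col, sprintf("row %d (protein %s), column %s",
                   seq_along(col), pid, colnames(df)[j + 1L]))
  }
  quant_matrix(vals, scale = match.arg(scale))
}

#' Write a QuantMatrix as TSV
#' @param qm a [quant_matrix()]
#' @param path output path; missing cells are written as `NA`.
#' @export
write_quant_matrix <- function(qm, path) {
  stopifnot(inherits(qm, "QuantMatrix"))
  df <- data.frame(protein = protein_ids(qm), qm$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a sample annotation table
#'
#' TSV with header columns `sample_id`, `cohort` (`discovery` or
#' `validation`), `group` (`case` or `control`), and optional numeric
#' `bcva_logmar` and `diabetes_years` covariates (missing = `NA`).
#'
#' @param path file path.
#' @return a `data.frame` with one row per sample.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "cohort", "group")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("sample table lacks column(s): ",
                         paste(miss, collapse = ", "))
  validate_sample_table(data.frame(
    sample_id = df$sample_id,
    cohort = df$cohort,
    group = df$group,
    bcva_logmar = if ("bcva_logmar" %in% colnames(df))
      .parse_cells(df$bcva_logmar, paste("bcva_logmar row", seq_len(nrow(df))))
    else NA_real_,
    diabetes_years = if ("diabetes_years" %in% colnames(df))
      .parse_cells(df$diabetes_years,
                   paste("diabetes_years row", seq_len(nrow(df))))
    else NA_real_,
    stringsAsFactors = FALSE))
}

validate_sample_table <- function(samples) {
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample table")
  if (!all(samples$cohort %in% c("discovery", "validation")))
    stop("cohort must be 'discovery' or 'validation'")
  if (!all(samples$group %in% c("case", "control")))
    stop("group must be 'case' or 'control'")
  samples
}

#' @rdname read_sample_table
#' @param samples a sample table `data.frame`.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then one or more members. Duplicate members within a set are removed
#' with a warning; duplicate set names are an error.
#'
#' @param path file path.
#' @return a `GeneSetCollection`: list with `name`, `description` character
#'   vectors and `members`, a named list of unique member vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 fields", short[[1L]]))
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name: ", nm[duplicated(nm)][[1L]])
  members <- lapply(parts, function(p) {
    m <- p[-(1:2)]
    if (anyDuplicated(m)) {
      warning(sprintf("set %s: %d duplicate member(s) removed", p[[1L]],
                      sum(duplicated(m))))
      m <- unique(m)
    }
    m
  })
  names(members) <- nm
  gene_set_collection(nm, vapply(parts, `[[`, "", 2L), members)
}

#' @rdname read_gmt
#' @param name,description,members parallel set names, free-text
#'   descriptions and a list of member id vectors.
#' @export
gene_set_collection <- function(name, description = rep("", length(name)),
                                members) {
  if (anyDuplicated(name)) stop("duplicate gene-set name")
  if (any(lengths(members) == 0L)) stop("empty gene set")
  names(members) <- name
  structure(list(name = name, description = description, members = members),
            class = "GeneSetCollection")
}

#' @rdname read_gmt
#' @param collection a `GeneSetCollection`.
#' @export
write_gmt <- function(collection, path) {
  lines <- mapply(function(n, d, m) paste(c(n, d, m), collapse = "\t"),
                  collection$name, collection$description,
                  collection$members)
  writeLines(lines, path)
  invisible(path)
}

#' Read a STRING-style interaction edge list
#'
#' Whitespace- or tab-separated columns `node_a`, `node_b`, `combined_score`
#' (a header line is detected and skipped). STRING exports scores either as
#' 0-999 integers or 0-1 reals: if any score exceeds 1 the whole column is
#' divided by 1000. Self-loops are dropped and `(a,b)`/`(b,a)` duplicates
#' merged keeping the maximum score; both actions are reported via a message
#' with counts so no record disappears silently.
#'
#' @param path file path.
#' @return a `data.frame` with columns `node_a`, `node_b`, `combined_score`
#'   (in `[0,1]`), nodes canonically ordered within each row
#'   (`node_a < node_b`).
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  if (length(parts) && is.na(suppressWarnings(as.numeric(parts[[1L]][3L]))))
    parts <- parts[-1L]  # header
  if (!length(parts)) return(edge_list(character(), character(), numeric()))
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad)) stop(sprintf("edge-list line with < 3 fields (line %d)",
                                bad[[1L]]))
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  s <- .parse_cells(vapply(parts, `[[`, "", 3L),
                    sprintf("edge list line %d", seq_along(parts)))
  if (anyNA(s)) stop("missing combined score in edge list")
  if (any(s > 1)) s <- s / 1000
  if (any(s < 0 | s > 1)) stop("combined score outside [0,1] after rescaling")
  edge_list(a, b, s)
}

#' @rdname read_edge_list
#' @param node_a,node_b,combined_score parallel edge record vectors.
#' @export
edge_list <- function(node_a, node_b, combined_score) {
  stopifnot(length(node_a) == length(node_b),
            length(node_a) == length(combined_score))
  if (any(combined_score < 0 | combined_score > 1, na.rm = TRUE))
    stop("combined score outside [0,1]")
  keep <- node_a != node_b
  if (any(!keep))
    message(sum(!keep), " self-loop(s) dropped")
  a <- pmin(node_a[keep], node_b[keep])
  b <- pmax(node_a[keep], node_b[keep])
  s <- combined_score[keep]
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    message(sum(duplicated(key)), " duplicate edge(s) merged (max score kept)")
    s <- vapply(split(s, key), max, 0)[unique(key)]
    a <- a[!duplicated(key)]; b <- b[!duplicated(key)]
  }
  data.frame(node_a = a, node_b = b, combined_score = unname(s),
             stringsAsFactors = FALSE)
}

#' @rdname read_edge_list
#' @param edges an edge-list `data.frame`.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
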