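#' Read a compound property table
#'
#' Parses a TCMSP-style table of candidate compounds with oral
#' bioavailability (OB, percent) and drug-likeness (DL, in \[0, 1\]) columns,
#' the two ADMET properties used by [screenCompounds()]. The field separator
#' is sniffed from the header line (tab or comma). Column headers are matched
#' case-insensitively after stripping spaces/underscores; pass `columns` to
#' override the mapping.
#'
#' @param path path to a TSV or CSV file with a header row.
#' @param columns named character vector mapping the canonical names
#'   `molId`, `name`, `ob`, `dl` to header names in the file.
#' @return data.frame with columns `molId`, `name`, `ob`, `dl`, one row per
#'   compound, input order preserved.
#' @examples
#' tbl <- readCompoundTable(system.file("extdata", "aa_compounds.tsv",
#'                                      package = "netpharm"))
#' head(tbl)
#' @export
readCompoundTable <- function(path, columns = NULL) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stopf("'%s' is empty: no header row", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  canon <- function(x) gsub("[ _.]", "", tolower(x))
  want <- list(molId = c("molid", "id", "moleculeid"),
               name = c("moleculename", "name", "molecule", "compound"),
               ob = "ob", dl = "dl")
  if (!is.null(columns)) for (nm in names(columns)) want[[nm]] <- canon(columns[[nm]])
  hdr <- canon(names(df))
  idx <- vapply(want, function(aliases) {
    hit <- which(hdr %in% aliases)
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  if (anyNA(idx)) {
    stopf("compound table '%s' is missing column(s): %s", path,
          paste(names(idx)[is.na(idx)], collapse = ", "))
  }
  out <- data.frame(molId = trimws(df[[idx[["molId"]]]]),
                    name = trimws(df[[idx[["name"]]]]),
                    ob = rep(NA_real_, nrow(df)), dl = rep(NA_real_, nrow(df)),
                    stringsAsFactors = FALSE)
  for (col in c("ob", "dl")) {
    raw <- trimws(df[[idx[[col]]]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & nzchar(raw))
    bad <- c(bad, which(!nzchar(raw)))
    if (length(bad)) {
      stopf("non-numeric %s value '%s' at data row %d of '%s'",
            toupper(col), raw[min(bad)], min(bad), path)
    }
    out[[col]] <- val
  }
  if (any(!nzchar(out$molId))) stopf("empty compound id in '%s'", path)
  if (anyDuplicated(out$molId)) {
    stopf("duplicate compound id(s) in '%s': %s", path,
          paste(unique(out$molId[duplicated(out$molId)]), collapse = ", "))
  }
  if (any(out$ob < 0)) stopf("negative OB value in '%s'", path)
  if (any(out$dl < 0 | out$dl > 1)) stopf("DL outside [0, 1] in '%s'", path)
  out
}

#' Read a plain gene-symbol list
#'
#' One symbol per line; `#` starts a comment (whole line or trailing).
#' Symbols are normalized (trimmed, upper-cased) and deduplicated.
#'
#' @param path path to the list file.
#' @param name label for the resulting set (defaults to the file name).
#' @return a [GeneSet-class].
#' @export
readGeneList <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  GeneSet(lines[nzchar(trimws(lines))], name = name)
}

#' Read annotation sets in GMT format
#'
#' Standard tab-separated GMT: set name, description (discarded), then the
#' member gene symbols.
#'
#' @param path path to a `.gmt` file.
#' @return named list of [GeneSet-class] objects, one per line.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stopf("GMT line %d has %d field(s); need name, description and >= 1 gene",
            i, length(fields))
    }
    sets[[i]] <- GeneSet(fields[-(1:2)], name = fields[1L])
  }
  names(sets) <- vapply(sets, setName, character(1))
  sets
}

#' Read an undirected edge list (two-column TSV or SIF)
#'
#' Accepts STRING-style two-column exports and Cytoscape SIF (source,
#' interaction label, one or more targets); the dialect is detected per line
#' from the column count. The result is a simple undirected graph:
#' duplicate and reversed pairs are collapsed and self-loops are dropped
#' with a warning.
#'
#' @param path path to the edge file; fields separated by tabs or spaces.
#' @return an undirected simple `igraph` with a `name` vertex attribute.
#' @export
readEdgeList <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  from <- character(); to <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "[ \t]+")[[1L]]
    if (length(fields) == 1L) {
      stopf("edge list line %d has a single column: '%s'", i, lines[i])
    }
    if (length(fields) == 2L) {
      from <- c(from, fields[1L]); to <- c(to, fields[2L])
    } else {
      # SIF: node, interaction type, target(s)
      tgt <- fields[-(1:2)]
      from <- c(from, rep(fields[1L], length(tgt))); to <- c(to, tgt)
    }
  }
  loops <- from == to
  if (any(loops)) {
    warnf("dropped %d self-loop(s) (e.g. '%s')", sum(loops), from[which(loops)[1L]])
    from <- from[!loops]; to <- to[!loops]
  }
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to,
                                                stringsAsFactors = FALSE),
                                     directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read a compound-to-target map
#'
#' Two-column TSV (compound id, gene symbol), one pair per row, as exported
#' from a drug-target database.
#'
#' @param path path to the TSV file.
#' @return named list of [GeneSet-class] target sets, one per compound,
#'   in first-appearance order.
#' @export
readTargetMap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("target map '%s' needs two tab-separated columns", path)
  split_genes <- split(df[[2L]], factor(df[[1L]], levels = unique(df[[1L]])))
  lapply(setNames(names(split_genes), names(split_genes)),
         function(cmp) GeneSet(split_genes[[cmp]], name = cmp))
}

canonicalEdgeTable <- function(g) {
  if (igraph::ecount(g) == 0L) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  swap <- el[, 1L] > el[, 2L]
  el[swap, ] <- el[swap, c(2L, 1L)]
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  data.frame(from = el[, 1L], to = el[, 2L], stringsAsFactors = FALSE)
}

#' @describeIn writeResults tables as CSV (no row names).
#' @export
setMethod("writeResults", "data.frame", function(obj, path, ...) {
  utils::write.csv(obj, path, row.names = FALSE, quote = TRUE)
  invisible(path)
})

#' @describeIn writeResults graphs as a canonical sorted two-column TSV
#'   edge list (lexicographically smaller endpoint first).
#' @export
setMethod("writeResults", "igraph", function(obj, path, ...) {
  utils::write.table(canonicalEdgeTable(obj), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
})

#' @describeIn writeResults gene sets as one symbol per line (sorted).
#' @export
setMethod("writeResults", "GeneSet", function(obj, path, ...) {
  writeLines(sort(genes(obj)), path)
  invisible(path)
})

#' @describeIn writeResults list-like run summaries as JSON.
#' @export
setMethod("writeResults", "list", function(obj, path, ...) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
})
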