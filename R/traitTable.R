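#' @rdname accessors
#' @aliases traitValues,TraitTable-method
setMethod("traitValues", "TraitTable", function(x) x@values)

#' @rdname accessors
#' @aliases observedMask,TraitTable-method
setMethod("observedMask", "TraitTable", function(x) x@observed)

#' @rdname accessors
#' @aliases columnKinds,TraitTable-method
setMethod("columnKinds", "TraitTable", function(x) x@columnKinds)

#' @rdname accessors
#' @aliases scaleTags,TraitTable-method
setMethod("scaleTags", "TraitTable", function(x) x@scaleTags)

setMethod("show", "TraitTable", function(object) {
  v <- traitValues(object)
  nMiss <- sum(!observedMask(object))
  cat(sprintf("TraitTable: %d specimens x %d columns (%d missing cells)\n",
              nrow(v), ncol(v), nMiss))
  kinds <- columnKinds(object)
  cont <- names(kinds)[kinds == "continuous"]
  cat("  continuous :", paste0(cont, " [", scaleTags(object)[cont], "]",
                               collapse = ", "), "\n")
  catg <- names(kinds)[kinds == "categorical"]
  if (length(catg)) cat("  categorical:", paste(catg, collapse = ", "), "\n")
})

#' Read a specimen-level trait table from disk
#'
#' Parses a delimited text file (or the first sheet of an XLSX workbook)
#' into a [TraitTable-class]. Cells that are empty or equal one of
#' `missingTokens` are flagged missing; continuous cells are parsed as
#' numbers, and a non-numeric, non-missing entry in a continuous column
#' is an error naming the offending row and column.
#'
#' @param path file path.
#' @param format `"csv"`, `"tsv"` or `"xlsx"`; defaults from the file
#'   extension.
#' @param columnKinds named character vector assigning `"continuous"` /
#'   `"categorical"` to columns; unassigned columns are inferred.
#' @param missingTokens character vector of sentinel strings treated as
#'   missing (default empty string, `"NA"`, `"NaN"`).
#' @return A [TraitTable-class] with all continuous columns tagged
#'   `"raw"`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("Wing.Length,Species", "68.1,a", ",b", "70.2,a"), f)
#' tt <- readTraitTable(f, columnKinds = c(Wing.Length = "continuous",
#'                                         Species = "categorical"))
#' sum(!observedMask(tt))  # one missing cell
#' @export
readTraitTable <- function(path, format = c("auto", "csv", "tsv", "xlsx"),
                           columnKinds = NULL,
                           missingTokens = c("", "NA", "NaN")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     xlsx = "xlsx",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- switch(format,
    csv = tryCatch(
      utils::read.csv(path, colClasses = "character", check.names = FALSE,
                      na.strings = character()),
      error = function(e) stop("unparseable csv file: ", conditionMessage(e))),
    tsv = tryCatch(
      utils::read.delim(path, colClasses = "character", check.names = FALSE,
                        na.strings = character()),
      error = function(e) stop("unparseable tsv file: ", conditionMessage(e))),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading xlsx requires the 'readxl' package")
      }
      as.data.frame(lapply(
        readxl::read_excel(path, sheet = 1, col_types = "text"),
        function(x) ifelse(is.na(x), "", x)
      ), check.names = FALSE, stringsAsFactors = FALSE)
    }
  )
  parseTraitFrame(raw, columnKinds, missingTokens)
}

# Shared text-frame -> TraitTable conversion.
parseTraitFrame <- function(raw, columnKinds, missingTokens) {
  n <- nrow(raw)
  isMissing <- function(x) is.na(x) | trimws(x) %in% missingTokens
  inferred <- vapply(raw, function(x) {
    obs <- x[!isMissing(x)]
    if (length(obs) == 0L) return("continuous")
    if (all(!is.na(suppressWarnings(as.numeric(obs))))) "continuous"
    else "categorical"
  }, character(1))
  kinds <- inferred
  if (!is.null(columnKinds)) {
    known <- intersect(names(columnKinds), names(kinds))
    kinds[known] <- columnKinds[known]
  }
  values <- raw
  for (j in seq_along(raw)) {
    cn <- colnames(raw)[j]
    miss <- isMissing(raw[[j]])
    if (kinds[j] == "continuous") {
      num <- suppressWarnings(as.numeric(raw[[j]]))
      bad <- which(!miss & is.na(num))
      if (length(bad)) {
        stop(sprintf(
          "cannot parse continuous cell at row %d, column '%s': '%s'",
          bad[1], cn, raw[bad[1], j]))
      }
      num[miss] <- NA_real_
      values[[j]] <- num
    } else {
      x <- as.character(raw[[j]])
      x[miss] <- NA_character_
      values[[j]] <- x
    }
  }
  TraitTable(values, columnKinds = kinds)
}

#' Write a TraitTable to a delimited file
#'
#' Values are written at full double precision so that a write/read round
#' trip preserves observed values, masks and column order. Missing cells
#' are written as empty fields.
#'
#' @param table a [TraitTable-class].
#' @param path output file path.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @return `path`, invisibly.
#' @export
writeTraitTable <- function(table, path, sep = ",") {
  v <- traitValues(table)
  out <- v
  for (j in seq_along(out)) {
    x <- out[[j]]
    if (is.numeric(x)) {
      s <- sprintf("%.17g", x)
      s[is.na(x)] <- ""
      out[[j]] <- s
    } else {
      x[is.na(x)] <- ""
      out[[j]] <- x
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Declarative record-cleaning rules
#'
#' @param requiredColumns columns a record must have observed to survive.
#' @param qcFlagColumn optional quality-control column; records whose
#'   value is not in `qcPassValues` are dropped.
#' @param qcPassValues accepted tokens for `qcFlagColumn`.
#' @param dropAllMissingRows drop rows whose every continuous trait is
#'   missing.
#' @return A `CleaningConfig` list.
#' @export
cleaningConfig <- function(requiredColumns = character(),
                           qcFlagColumn = NULL,
                           qcPassValues = character(),
                           dropAllMissingRows = TRUE) {
  structure(list(requiredColumns = requiredColumns,
                 qcFlagColumn = qcFlagColumn,
                 qcPassValues = qcPassValues,
                 dropAllMissingRows = dropAllMissingRows),
            class = "CleaningConfig")
}

#' Remove records failing basic quality rules
#'
#' Applies the rules of a [cleaningConfig()] in order (required columns,
#' QC flag, all-missing rows) and reports the number of rows each rule
#' removed. Row order is preserved; an empty result is legal.
#'
#' @param table a [TraitTable-class].
#' @param rules a [cleaningConfig()].
#' @param verbose emit a per-rule removal message.
#' @return The cleaned [TraitTable-class].
#' @export
cleanTable <- function(table, rules = cleaningConfig(), verbose = FALSE) {
  stopifnot(inherits(rules, "CleaningConfig"))
  v <- traitValues(table)
  m <- observedMask(table)
  missingRefs <- setdiff(c(rules$requiredColumns, rules$qcFlagColumn),
                         colnames(v))
  if (length(missingRefs)) {
    stop("cleaning rules reference absent columns: ",
         paste(missingRefs, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(v))
  removed <- c(required = 0L, qc = 0L, allMissing = 0L)
  if (length(rules$requiredColumns)) {
    ok <- rowSums(!m[, rules$requiredColumns, drop = FALSE]) == 0L
    removed["required"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (!is.null(rules$qcFlagColumn)) {
    flag <- as.character(v[[rules$qcFlagColumn]])
    ok <- !is.na(flag) & flag %in% rules$qcPassValues
    removed["qc"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (isTRUE(rules$dropAllMissingRows)) {
    kinds <- columnKinds(table)
    cont <- names(kinds)[kinds == "continuous"]
    if (length(cont)) {
      ok <- rowSums(m[, cont, drop = FALSE]) > 0L
      removed["allMissing"] <- sum(keep & !ok)
      keep <- keep & ok
    }
  }
  if (verbose) {
    message(sprintf(
      "cleaning removed %d rows (required fields %d, QC %d, all-missing %d); %d remain",
      sum(!keep), removed["required"], removed["qc"], removed["allMissing"],
      sum(keep)))
  }
  subsetRows(table, which(keep))
}

#' Natural-log transform of strictly positive continuous columns
#'
#' Replaces observed values by their natural logarithm and retags the
#' columns `"log"`. Masks are unchanged; an observed non-positive value
#' is an error naming the row and column (never silently dropped).
#'
#' @param table a [TraitTable-class].
#' @param columns continuous columns to transform (default: all
#'   raw-tagged continuous columns).
#' @return The transformed [TraitTable-class].
#' @examples
#' tt <- TraitTable(data.frame(Mass = c(1, exp(1))))
#' traitValues(logTransform(tt, "Mass"))$Mass  # 0, 1
#' @export
logTransform <- function(table, columns = NULL) {
  kinds <- columnKinds(table)
  tags <- scaleTags(table)
  if (is.null(columns)) {
    columns <- names(tags)[tags == "raw"]
  }
  notCont <- columns[kinds[columns] != "continuous"]
  if (length(notCont) || anyNA(kinds[columns])) {
    stop("log transform applies to continuous columns only: ",
         paste(c(notCont, columns[is.na(kinds[columns])]), collapse = ", "))
  }
  v <- traitValues(table)
  m <- observedMask(table)
  for (cn in columns) {
    if (identical(tags[[cn]], "log")) {
      stop("column '", cn, "' is already log-scale")
    }
    x <- v[[cn]]
    obs <- m[, match(cn, colnames(v))]
    bad <- which(obs & x <= 0)
    if (length(bad)) {
      stop(sprintf(
        "non-positive value %g at row %d, column '%s': log transform requires strictly positive values",
        x[bad[1]], bad[1], cn))
    }
    x[obs] <- log(x[obs])
    v[[cn]] <- x
    tags[[cn]] <- "log"
  }
  TraitTable(v, columnKinds = kinds, observed = m, scaleTags = tags)
}

#' Integer-encode categorical columns
#'
#' Each distinct category token is mapped to a consecutive integer code
#' starting at 0, in first-appearance order (deterministic). Missing
#' categorical cells stay masked. When a stored map is supplied, tokens
#' unseen at training time map to the reserved code `-1` with a warning.
#'
#' @param table a [TraitTable-class].
#' @param columns categorical columns to encode (default: all).
#' @param map optional `EncodingMap` from a previous call, applied instead
#'   of being learned.
#' @return `list(table = encoded TraitTable, map = EncodingMap)`. The map
#'   is a named list (one entry per column) of named integer vectors;
#'   `decodeCategorical()` inverts it.
#' @examples
#' tt <- TraitTable(data.frame(Species = c("sparrow", "crow", "sparrow")),
#'                  columnKinds = c(Species = "categorical"))
#' enc <- encodeCategoricals(tt, "Species")
#' traitValues(enc$table)$Species  # 0 1 0
#' @export
encodeCategoricals <- function(table, columns = NULL, map = NULL) {
  kinds <- columnKinds(table)
  if (is.null(columns)) {
    columns <- names(kinds)[kinds == "categorical"]
    # only un-encoded (character) columns
    columns <- columns[vapply(traitValues(table)[columns], is.character,
                              logical(1))]
  }
  notCat <- columns[kinds[columns] != "categorical"]
  if (length(notCat)) {
    stop("not categorical columns: ", paste(notCat, collapse = ", "))
  }
  v <- traitValues(table)
  m <- observedMask(table)
  if (is.null(map)) map <- structure(list(), class = "EncodingMap")
  for (cn in columns) {
    x <- as.character(v[[cn]])
    obs <- m[, match(cn, colnames(v))]
    if (is.null(map[[cn]])) {
      tokens <- unique(x[obs])
      map[[cn]] <- stats::setNames(seq_along(tokens) - 1L, tokens)
    }
    codes <- unname(map[[cn]][x])
    unseen <- obs & is.na(codes)
    if (any(unseen)) {
      warning(sprintf(
        "%d value(s) in '%s' unseen at encoding time mapped to reserved code -1 (e.g. '%s')",
        sum(unseen), cn, x[which(unseen)[1]]))
      codes[unseen] <- -1L
    }
    codes[!obs] <- NA_integer_
    v[[cn]] <- as.integer(codes)
  }
  class(map) <- "EncodingMap"
  list(
    table = TraitTable(v, columnKinds = kinds, observed = m,
                       scaleTags = scaleTags(table)),
    map = map
  )
}

#' @rdname encodeCategoricals
#' @param codes integer codes to invert.
#' @param column column name within the map.
#' @export
decodeCategorical <- function(map, column, codes) {
  tokens <- names(map[[column]])
  out <- tokens[match(codes, map[[column]])]
  out[codes == -1L] <- NA_character_
  out
}

#' Pairwise-complete Pearson correlations with a target trait
#'
#' For each candidate predictor, the sample Pearson correlation with the
#' target is computed over the rows where both are observed. Candidates
#' with fewer than 2 complete pairs or zero variance are reported with
#' `r = NA` and flagged unusable for screening.
#'
#' @param table a [TraitTable-class]; candidates must be numeric (encode
#'   categoricals first).
#' @param target continuous target column name.
#' @param candidates candidate predictor names (default: every numeric
#'   column except the target).
#' @return A `CorrelationReport` data.frame with columns `feature`, `r`,
#'   `nPairs`, `usable`, carrying the target name as attribute `target`.
#' @export
pairwisePearson <- function(table, target, candidates = NULL) {
  v <- traitValues(table)
  if (!target %in% colnames(v)) stop("target column '", target, "' absent")
  if (!is.numeric(v[[target]])) stop("target must be numeric")
  if (is.null(candidates)) {
    candidates <- setdiff(colnames(v)[vapply(v, is.numeric, logical(1))],
                          target)
  }
  m <- observedMask(table)
  ty <- v[[target]]
  tObs <- m[, match(target, colnames(v))]
  rows <- lapply(candidates, function(cn) {
    x <- v[[cn]]
    if (!is.numeric(x)) stop("candidate '", cn, "' is not numeric")
    both <- tObs & m[, match(cn, colnames(v))]
    n <- sum(both)
    if (n < 2L || stats::sd(x[both]) == 0 || stats::sd(ty[both]) == 0) {
      data.frame(feature = cn, r = NA_real_, nPairs = n, usable = FALSE)
    } else {
      data.frame(feature = cn, r = stats::cor(x[both], ty[both]),
                 nPairs = n, usable = TRUE)
    }
  })
  rep <- do.call(rbind, rows)
  attr(rep, "target") <- target
  class(rep) <- c("CorrelationReport", "data.frame")
  rep
}

#' Random 70/30-style row split
#'
#' Partitions the rows into disjoint training and validation tables.
#' The partition is a pure function of `(seed, nrow)`: the same seed on
#' the same table size yields the identical index sets, so one split can
#' be reused consistently across methods and feature combinations.
#'
#' @param table a [TraitTable-class] with at least 2 rows.
#' @param trainFraction proportion in (0, 1); the training set receives
#'   `round(n * trainFraction)` rows.
#' @param seed integer seed.
#' @return `list(train = , validation = , trainIdx = , valIdx = )`.
#' @export
splitTable <- function(table, trainFraction = 0.7, seed = 1L) {
  n <- nrow(traitValues(table))
  if (n < 2L) stop("need at least 2 rows to split")
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must be in (0, 1)")
  }
  nTrain <- round(n * trainFraction)
  nTrain <- max(1L, min(n - 1L, nTrain))
  idx <- withSeed(seed, sample.int(n, nTrain))
  trainIdx <- sort(idx)
  valIdx <- setdiff(seq_len(n), trainIdx)
  list(train = subsetRows(table, trainIdx),
       validation = subsetRows(table, valIdx),
       trainIdx = trainIdx, valIdx = valIdx)
}
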