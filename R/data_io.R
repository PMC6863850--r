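#' Read a drug-target association table
#'
#' Reads a two-column TSV (\code{drug_id}, \code{target_id}), one row per
#' association, with an optional header line. Multi-target drugs are
#' aggregated into target sets. Duplicate associations are deduplicated
#' with a message; rows that do not have exactly two fields are a hard
#' error naming the offending line.
#'
#' @param path file path.
#' @return named list mapping each drug ID to a character vector of target
#'   IDs. Absence of a drug from the list is distinct from an empty set.
#' @export
readTargetTable <- function(path) {
  if (!file.exists(path)) stopf("target table not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (length(fields[[1]]) == 2L &&
      all(tolower(trimws(fields[[1]])) %in%
          c("drug_id", "target_id", "drug", "target")))
    start <- 2L
  if (start > length(lines)) return(structure(list(), names = character(0)))
  fields <- fields[start:length(fields)]
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stopf("malformed association row at line %d of %s (expected 2 fields, got %d)",
          bad[1] + start - 1L, path, lengths(fields)[bad[1]])
  drug <- vapply(fields, `[[`, character(1), 1L)
  target <- vapply(fields, `[[`, character(1), 2L)
  if (any(!nzchar(drug)) || any(!nzchar(target)))
    stopf("empty drug or target ID in %s", path)
  dup <- duplicated(paste(drug, target, sep = "\r"))
  if (any(dup)) {
    message(sprintf("readTargetTable: deduplicated %d duplicate association(s)",
                    sum(dup)))
    drug <- drug[!dup]; target <- target[!dup]
  }
  split(target, factor(drug, levels = unique(drug)))
}

#' Write a drug-target association table
#' @param targets named list mapping drug ID to character vector of targets.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeTargetTable <- function(targets, path) {
  drug <- rep(names(targets), lengths(targets))
  df <- data.frame(drug_id = drug, target_id = unlist(targets, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a numeric profile matrix (drugs x conditions)
#'
#' CSV with drug IDs in the first column and condition IDs in the header.
#' Blank cells are missing values (\code{NA}), never zero. Ragged rows and
#' non-numeric non-blank cells are hard errors.
#'
#' @param path file path.
#' @return numeric matrix with drug IDs as rownames.
#' @export
readProfileMatrix <- function(path) {
  if (!file.exists(path)) stopf("profile matrix not found: %s", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"", blank.lines.skip = TRUE)
  if (length(unique(nf)) > 1L)
    stopf("ragged rows in %s: field counts %s", path,
          paste(unique(nf), collapse = ", "))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        row.names = NULL)
  if (!nrow(df)) {
    m <- matrix(numeric(0), 0, ncol(df) - 1L,
                dimnames = list(NULL, colnames(df)[-1]))
    return(m)
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) stopf("duplicate drug IDs in %s", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  blank <- !nzchar(trimws(vals)) | is.na(vals)
  num <- suppressWarnings(as.numeric(vals))
  badcell <- which(!blank & is.na(num))
  if (length(badcell))
    stopf("non-numeric cell '%s' in %s", vals[badcell[1]], path)
  m <- matrix(num, nrow(vals), ncol(vals),
              dimnames = list(ids, colnames(vals)))
  m
}

#' Write a numeric profile matrix
#' @param m numeric matrix with drug IDs as rownames; \code{NA} entries are
#'   written as blank cells.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeProfileMatrix <- function(m, path) {
  df <- data.frame(drug_id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  df[-1][is.na(m)] <- ""
  utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SMILES file
#'
#' Whitespace-delimited, one molecule per line: SMILES string then drug ID.
#' Unparseable SMILES are reported via a warning and skipped, never silently
#' dropped. Duplicate drug IDs are a hard error.
#'
#' @param path file path.
#' @return data.frame with columns \code{drug_id} and \code{smiles}
#'   (parseable records only).
#' @export
readSmilesFile <- function(path) {
  if (!file.exists(path)) stopf("SMILES file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(drug_id = character(0), smiles = character(0)))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  if (any(lengths(fields) < 2L))
    stopf("line %d of %s lacks an ID field", which(lengths(fields) < 2L)[1], path)
  smi <- vapply(fields, `[[`, character(1), 1L)
  ids <- vapply(fields, `[[`, character(1), 2L)
  if (anyDuplicated(ids))
    stopf("duplicate drug ID '%s' in %s", ids[duplicated(ids)][1], path)
  ok <- vapply(smi, smilesIsValid, logical(1))
  if (any(!ok))
    warnf("readSmilesFile: skipped %d unparseable SMILES (%s)", sum(!ok),
          paste(ids[!ok], collapse = ", "))
  data.frame(drug_id = ids[ok], smiles = smi[ok])
}

#' Serialize a fitted TLR model to JSON
#'
#' Writes every bin edge, raw ratio, fit coefficient, pseudocount and
#' imputation median at 17 significant digits, which round-trips IEEE
#' doubles exactly: \code{loadModel(saveModel(m))} reproduces all TLRs
#' bit-exactly.
#'
#' @param model a \linkS4class{TLRModel}.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "TLRModel"))
  payload <- list(
    format = "DrugBayes-TLRModel",
    version = model@version,
    channels = lapply(model@models, function(m) list(
      channel = m@channel, breaks = m@breaks, ratios = m@ratios,
      countsST = unname(m@counts["ST", ]),
      countsNonST = unname(m@counts["nonST", ]),
      a = m@coef[["a"]], b = m@coef[["b"]],
      median = m@median, alpha = m@alpha, range = m@range)))
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Load a serialized TLR model
#' @param path JSON path written by \code{\link{saveModel}}.
#' @return a \linkS4class{TLRModel}.
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  payload <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE,
                                         simplifyDataFrame = FALSE),
                      error = function(e) stopf("corrupt model file %s: %s",
                                                path, conditionMessage(e)))
  if (!identical(payload$format, "DrugBayes-TLRModel"))
    stopf("%s is not a DrugBayes model serialization", path)
  if (!identical(as.character(payload$version), "1"))
    stopf("unsupported model format version '%s'", payload$version)
  models <- lapply(payload$channels, function(ch) {
    counts <- rbind(ST = as.numeric(ch$countsST),
                    nonST = as.numeric(ch$countsNonST))
    new("LikelihoodModel", channel = ch$channel,
        breaks = as.numeric(ch$breaks), ratios = as.numeric(ch$ratios),
        counts = counts, coef = c(a = ch$a, b = ch$b),
        median = ch$median, alpha = ch$alpha, range = as.numeric(ch$range))
  })
  names(models) <- vapply(models, function(m) m@channel, character(1))
  new("TLRModel", models = models, version = "1")
}

#' Write a similarity matrix as value + mask CSV pair
#'
#' The value CSV stores scores with masked pairs as blank cells; the mask
#' CSV stores 1 where the score is defined and 0 where masked.
#'
#' @param sim a \linkS4class{SimilarityMatrix}.
#' @param path value CSV path.
#' @param maskPath mask CSV path; default replaces the extension with
#'   \code{_mask.csv}.
#' @return invisibly, \code{c(path, maskPath)}.
#' @export
writeSimilarityMatrix <- function(sim, path,
                                  maskPath = sub("\\.csv$", "_mask.csv", path)) {
  stopifnot(is(sim, "SimilarityMatrix"))
  writeProfileMatrix(sim@scores, path)
  mask <- (!is.na(sim@scores)) * 1
  dimnames(mask) <- dimnames(sim@scores)
  writeProfileMatrix(mask, maskPath)
  invisible(c(path, maskPath))
}

#' Read a similarity matrix written by \code{\link{writeSimilarityMatrix}}
#' @param path value CSV path.
#' @param channel channel name to attach.
#' @param range score range of the channel.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
readSimilarityMatrix <- function(path, channel, range) {
  m <- readProfileMatrix(path)
  colnames(m) <- rownames(m)
  new("SimilarityMatrix", channel = channel, scores = m, range = range)
}

#' Read a binary feature table (bioassay outcomes or side-effect terms)
#'
#' Two dialects share one reader. \code{mode = "bioassay"}: long TSV with
#' columns \code{drug_id}, \code{feature_id}, \code{outcome} in
#' \{\code{positive}, \code{negative}\}; a drug's tested set is the set of
#' features it has any outcome for. \code{mode = "presence"} (side effects):
#' two-column TSV \code{drug_id}, \code{feature_id} listing present terms;
#' every drug counts as tested on the full vocabulary.
#'
#' @param path file path.
#' @param mode \code{"bioassay"} or \code{"presence"}.
#' @return list with named lists \code{positives} and \code{tested}
#'   (for \code{"presence"}, \code{tested} is \code{NULL} meaning the full
#'   vocabulary) and character \code{vocabulary}.
#' @export
readBinaryTable <- function(path, mode = c("bioassay", "presence")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stopf("binary feature table not found: %s", path)
  want <- if (mode == "bioassay") 3L else 2L
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(list(positives = list(), tested = if (mode == "bioassay") list(),
                vocabulary = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- if (tolower(fields[[1]][1]) == "drug_id") 2L else 1L
  fields <- fields[seq.int(start, length(fields))]
  bad <- which(lengths(fields) != want)
  if (length(bad))
    stopf("malformed row at line %d of %s (expected %d fields)",
          bad[1] + start - 1L, path, want)
  drug <- vapply(fields, `[[`, character(1), 1L)
  feat <- vapply(fields, `[[`, character(1), 2L)
  if (mode == "bioassay") {
    out <- vapply(fields, `[[`, character(1), 3L)
    if (!all(out %in% c("positive", "negative")))
      stopf("bioassay outcome must be 'positive' or 'negative' in %s", path)
    dl <- factor(drug, levels = unique(drug))
    tested <- split(feat, dl)
    positives <- split(feat[out == "positive"],
                       factor(drug[out == "positive"], levels = levels(dl)))
    list(positives = lapply(positives, unique),
         tested = lapply(tested, unique),
         vocabulary = sort(unique(feat)))
  } else {
    dl <- factor(drug, levels = unique(drug))
    list(positives = lapply(split(feat, dl), unique), tested = NULL,
         vocabulary = sort(unique(feat)))
  }
}

#' Write a binary feature table
#' @param x list as returned by \code{\link{readBinaryTable}}.
#' @param path output TSV path.
#' @param mode \code{"bioassay"} or \code{"presence"}.
#' @return invisibly, the path.
#' @export
writeBinaryTable <- function(x, path, mode = c("bioassay", "presence")) {
  mode <- match.arg(mode)
  con <- file(path, "w")
  on.exit(close(con))
  if (mode == "bioassay") {
    writeLines("drug_id\tfeature_id\toutcome", con)
    for (d in names(x$tested)) {
      tested <- x$tested[[d]]
      pos <- tested %in% x$positives[[d]]
      writeLines(paste(d, tested, ifelse(pos, "positive", "negative"),
                       sep = "\t"), con)
    }
  } else {
    writeLines("drug_id\tfeature_id", con)
    for (d in names(x$positives))
      if (length(x$positives[[d]]))
        writeLines(paste(d, x$positives[[d]], sep = "\t"), con)
  }
  invisible(path)
}

#' Read a full channel directory (as written by \code{\link{writeUniverse}})
#'
#' Loads the public target table and whichever channel files are present
#' (\code{gi50.csv}, \code{cmap.csv}, \code{bioassay.tsv},
#' \code{sideeffect.tsv}, \code{structure_fp.csv}).
#'
#' @param dir directory path.
#' @return list with \code{targets} (named list) and \code{channels}
#'   (named list of channel payloads suitable for
#'   \code{\link{buildSimilarityMatrix}}).
#' @export
readUniverseDirectory <- function(dir) {
  if (!dir.exists(dir)) stopf("directory not found: %s", dir)
  targets <- readTargetTable(file.path(dir, "targets.tsv"))
  channels <- list()
  p <- function(f) file.path(dir, f)
  if (file.exists(p("gi50.csv"))) channels$gi50 <- readProfileMatrix(p("gi50.csv"))
  if (file.exists(p("cmap.csv"))) channels$cmap <- readProfileMatrix(p("cmap.csv"))
  if (file.exists(p("bioassay.tsv")))
    channels$bioassay <- readBinaryTable(p("bioassay.tsv"), mode = "bioassay")
  if (file.exists(p("sideeffect.tsv")))
    channels$sideeffect <- readBinaryTable(p("sideeffect.tsv"), mode = "presence")
  if (file.exists(p("structure_fp.csv")))
    channels$structure <- readProfileMatrix(p("structure_fp.csv"))
  if (!length(channels)) stopf("no channel files found under %s", dir)
  list(targets = targets, channels = channels)
}

#' Similarity matrices for a set of loaded channel payloads
#' @param channels named list as returned by
#'   \code{\link{readUniverseDirectory}}.
#' @return named list of \linkS4class{SimilarityMatrix}.
#' @export
channelSimilarities <- function(channels) {
  typeOf <- c(gi50 = "profile", cmap = "profile", bioassay = "binary",
              sideeffect = "binary", structure = "fingerprint",
              smiles = "smiles")
  out <- lapply(names(channels), function(ch) {
    ty <- if (ch %in% names(typeOf)) typeOf[[ch]] else
      stopf("unknown channel '%s'", ch)
    buildSimilarityMatrix(channels[[ch]], ch, type = ty)
  })
  names(out) <- names(channels)
  out
}
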