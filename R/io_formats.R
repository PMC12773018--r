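# Readers/writers for the formats the framework touches: FASTA, CSV/TSV
# dataset tables, TSV split manifests, and model artifact directories.

#' Read a multi-record FASTA file
#'
#' Sequences are uppercased and line wrapping is allowed; the id is the
#' first whitespace-delimited token of the header. A sequence line before
#' the first header is an error; an empty file yields an empty collection
#' with a warning.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0 ||
      length(readLines(path, n = 50, warn = FALSE)) == 0) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  first <- readLines(path, n = 1, warn = FALSE)
  if (!startsWith(trimws(first), ">"))
    stop("malformed FASTA: sequence before first header in ", path)
  x <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1)
  stats::setNames(toupper(as.character(x)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (names become headers).
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# delimiter auto-detection: tab wins if present in the header line
.detect_sep <- function(path) {
  header <- readLines(path, n = 1, warn = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a dataset table into a validated property dataset
#'
#' Expects columns `id`, `input`, `modality` and one column per property
#' label (the task's name); `protein_target` is carried through when
#' present. The delimiter (tab or comma) is auto-detected. Rows failing
#' record validation abort the read with their line numbers unless
#' `permissive = TRUE`, in which case they are skipped with a warning.
#'
#' @param path CSV/TSV file.
#' @param task A `property_task`.
#' @param permissive Skip invalid rows instead of erroring.
#' @return A `property_dataset`.
#' @export
read_dataset_table <- function(path, task, permissive = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path)
  required <- c("id", "input", "modality", task$name)
  header <- strsplit(readLines(path, n = 1, warn = FALSE), sep,
                     fixed = TRUE)[[1]]
  miss <- setdiff(required, header)
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, colClasses = list(
                            character = c("id", "input", "modality")))
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup) > 0)
    stop("duplicate id(s): ", paste(dup, collapse = ", "))
  y <- suppressWarnings(as.numeric(df[[task$name]]))
  bad_label <- which(!is.finite(y))
  if (length(bad_label) > 0 && !permissive)
    stop("unparseable label(s) at row(s): ",
         paste(bad_label, collapse = ", "))
  records <- list()
  failed <- integer(0)
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch({
      if (!is.finite(y[i])) stop("unparseable label")
      labels <- stats::setNames(list(y[i]), task$name)
      r <- peptide_record(df$id[i], df$modality[i], df$input[i],
                          labels = labels,
                          source = if ("source" %in% names(df))
                            df$source[i] else "table")
      if ("protein_target" %in% names(df))
        r$protein_target <- df$protein_target[i]
      r
    }, error = function(e) e)
    if (inherits(rec, "error")) failed <- c(failed, i)
    else records[[length(records) + 1]] <- rec
  }
  if (length(failed) > 0) {
    msg <- paste0("row(s) failing validation: ",
                  paste(failed, collapse = ", "))
    if (!permissive) stop(msg)
    warning(msg, " (skipped)")
  }
  property_dataset(task, records)
}

#' Write a property dataset to a table
#'
#' @param ds A `property_dataset`.
#' @param path Output path; delimiter chosen from the file extension
#'   (`.csv` comma, otherwise tab).
#' @export
write_dataset_table <- function(ds, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- data.frame(
    id = dataset_ids(ds),
    input = dataset_payloads(ds),
    modality = vapply(ds$records, function(r) r$modality, character(1)),
    stringsAsFactors = FALSE)
  df[[ds$task$name]] <- dataset_labels(ds)
  pt <- vapply(ds$records, function(r) r$protein_target %||% NA_character_,
               character(1))
  if (any(!is.na(pt))) df$protein_target <- pt
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

#' Write a split manifest
#'
#' TSV with one row per record (record_id, cluster_id, partition) and
#' commented header lines recording the method, parameters and seed so any
#' split is reproducible and auditable.
#'
#' @param split A `split_assignment`.
#' @param path Output path.
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "split_assignment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# method=", split$method),
    paste0("# params=", jsonlite::toJSON(split$params, auto_unbox = TRUE)),
    paste0("# seed=", split$seed),
    paste0("# train_frac=", split$train_frac),
    "record_id\tcluster_id\tpartition"), con)
  ids <- names(split$member_of)
  writeLines(paste(ids, split$member_of[ids],
                   split$record_partition[ids], sep = "\t"), con)
  invisible(path)
}

#' Read a split manifest
#'
#' @param path Manifest path written by [write_split_manifest()].
#' @return A `split_assignment` with method/params/seed restored.
#' @export
read_split_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- lines[startsWith(lines, "# ")]
  meta <- list()
  for (l in meta_lines) {
    kv <- sub("^# ", "", l)
    k <- sub("=.*$", "", kv)
    meta[[k]] <- sub("^[^=]*=", "", kv)
  }
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          colClasses = c("character", "integer",
                                         "character"))
  dup <- unique(df$record_id[duplicated(df$record_id)])
  if (length(dup) > 0)
    stop("record id(s) appearing more than once: ",
         paste(dup, collapse = ", "))
  if (!all(df$partition %in% c("train", "val")))
    stop("unknown partition token: ",
         paste(setdiff(unique(df$partition), c("train", "val")),
               collapse = ", "))
  # all records of one cluster must share one partition
  tab <- unique(df[, c("cluster_id", "partition")])
  bad <- tab$cluster_id[duplicated(tab$cluster_id)]
  if (length(bad) > 0)
    stop("cluster(s) spanning both partitions: ",
         paste(unique(bad), collapse = ", "))
  member_of <- stats::setNames(df$cluster_id, df$record_id)
  partition_of <- stats::setNames(tab$partition,
                                  as.character(tab$cluster_id))
  .split_assignment(
    partition_of, member_of,
    train_frac = as.numeric(meta$train_frac %||% NA),
    seed = as.integer(meta$seed %||% NA),
    method = meta$method %||% "unknown",
    params = if (is.null(meta$params)) list() else
      jsonlite::fromJSON(meta$params))
}

#' Save a trained head as a model artifact directory
#'
#' The artifact holds a JSON metadata document (task, modality, family,
#' hyperparameters, metrics, seed, featurizer spec), the fitted parameters,
#' a probe input/output pair for load-time self-verification, and per-file
#' checksums.
#'
#' @param head A `trained_head` (see [train_head()]).
#' @param dir Output directory (created if needed).
#' @export
save_model_artifact <- function(head, dir) {
  stopifnot(inherits(head, "trained_head"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(head$parameters, file.path(dir, "params.rds"), version = 2)
  probe_x <- head$probe$x
  probe_y <- predict_head(head, probe_x)
  saveRDS(list(x = probe_x, y = probe_y), file.path(dir, "probe.rds"),
          version = 2)
  meta <- list(
    format_version = 1L,
    family = head$spec$family, task_type = head$spec$task_type,
    input_mode = head$spec$input_mode, hyperparams = head$spec$hyperparams,
    loss = head$spec$loss, seed = head$spec$seed,
    featurizer_id = head$featurizer_id, task = head$task,
    modality = head$modality,
    metrics = if (is.null(head$metrics)) NULL else unclass(head$metrics),
    train_meta = head$train_meta,
    checksums = list(
      params.rds = unname(tools::md5sum(file.path(dir, "params.rds"))),
      probe.rds = unname(tools::md5sum(file.path(dir, "probe.rds")))))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a model artifact directory
#'
#' Verifies checksums and re-runs the stored probe input, requiring
#' bit-identical predictions.
#'
#' @param dir Artifact directory written by [save_model_artifact()].
#' @return A `trained_head`.
#' @export
load_model_artifact <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("no model artifact at ", dir)
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  if (!identical(as.integer(meta$format_version), 1L))
    stop("artifact format version mismatch")
  for (f in names(meta$checksums)) {
    got <- unname(tools::md5sum(file.path(dir, f)))
    if (!identical(got, meta$checksums[[f]]))
      stop("checksum failure for ", f)
  }
  parameters <- readRDS(file.path(dir, "params.rds"))
  probe <- readRDS(file.path(dir, "probe.rds"))
  spec <- head_spec(
    family = meta$family, task_type = meta$task_type,
    hyperparams = as.list(meta$hyperparams), seed = meta$seed,
    loss = meta$loss)
  head <- structure(
    list(spec = spec, parameters = parameters,
         train_meta = as.list(meta$train_meta), metrics = meta$metrics,
         featurizer_id = meta$featurizer_id, task = meta$task,
         modality = meta$modality, probe = probe),
    class = "trained_head")
  y2 <- predict_head(head, probe$x)
  if (!identical(unname(as.numeric(y2)), unname(as.numeric(probe$y))))
    stop("probe verification failed: predictions differ after reload")
  head
}
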