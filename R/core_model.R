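# Domain types shared by every stage: records, tasks, datasets.

PROPERTY_NAMES <- c("hemolysis", "non_fouling", "toxicity", "solubility",
                    "permeability_penetrance", "permeability_pampa",
                    "permeability_caco2", "half_life", "stability",
                    "binding_affinity")

#' Create a peptide record
#'
#' One peptide in one representation modality, together with its property
#' labels and provenance. Amino-acid (`"AA"`) payloads must use the 20
#' canonical residue letters and have length at least 2 (a single residue has
#' no peptide bond); noncanonical chemistry enters through the `"SMILES"`
#' modality, which accepts any string that later parses as a molecule.
#'
#' @param id Unique identifier (unique within a dataset).
#' @param modality `"AA"` or `"SMILES"`.
#' @param payload Residue string (AA) or SMILES string.
#' @param labels Named list/vector mapping property name to a binary (0/1)
#'   or finite continuous value.
#' @param source Free-text provenance tag.
#' @param cluster_id Optional integer cluster id.
#' @return An object of class `peptide_record`.
#' @export
peptide_record <- function(id, modality = c("AA", "SMILES"), payload,
                           labels = list(), source = "unknown",
                           cluster_id = NULL) {
  modality <- match.arg(modality)
  rec <- structure(
    list(id = as.character(id), modality = modality,
         payload = as.character(payload), labels = as.list(labels),
         source = source, cluster_id = cluster_id),
    class = "peptide_record")
  validate_record(rec)
}

#' Validate a peptide record
#'
#' Checks the record invariants and returns the record unchanged when they
#' hold (validation is idempotent). AA payloads are checked against the
#' canonical 20-letter alphabet; `U`, `O`, `B`, `Z`, `X` are rejected.
#' Labels must be finite; binary properties must be exactly 0 or 1.
#'
#' @param rec A `peptide_record`.
#' @return The validated record.
#' @export
validate_record <- function(rec) {
  stopifnot(inherits(rec, "peptide_record"))
  if (!nzchar(rec$payload)) stop("record '", rec$id, "': empty payload")
  if (rec$modality == "AA") {
    chars <- strsplit(rec$payload, "")[[1]]
    bad <- setdiff(unique(chars), AA_ALPHABET)
    if (length(bad) > 0)
      stop("record '", rec$id, "': non-canonical letters ",
           paste(bad, collapse = ", "))
    if (length(chars) < 2)
      stop("record '", rec$id, "': AA payload shorter than 2 residues")
  }
  for (nm in names(rec$labels)) {
    v <- rec$labels[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("record '", rec$id, "': label '", nm, "' is not a finite number")
  }
  rec
}

#' Define a property prediction task
#'
#' @param name One of the supported property names (see Details).
#' @param task_type `"binary"`, `"regression"` or `"paired_regression"`.
#' @param modalities Subset of `c("AA","SMILES")` the task accepts.
#' @param positive_meaning Human-readable meaning of label 1 / high values.
#' @param threshold Optional labeling threshold (e.g. -6.0 for the
#'   log Pexp high-permeability rule).
#' @details `permeability_pampa` and `permeability_caco2` are distinct tasks
#'   and are never merged: the two assays quantify different processes
#'   (passive membrane permeability vs intestinal absorption potential).
#'   `binding_affinity` is a paired task requiring a protein partner per
#'   record.
#' @return A `property_task`.
#' @export
property_task <- function(name,
                          task_type = c("binary", "regression",
                                        "paired_regression"),
                          modalities = "AA",
                          positive_meaning = "",
                          threshold = NULL) {
  name <- match.arg(name, PROPERTY_NAMES)
  task_type <- match.arg(task_type)
  stopifnot(all(modalities %in% c("AA", "SMILES")))
  if (name == "binding_affinity" && task_type != "paired_regression")
    stop("binding_affinity is a paired_regression task")
  structure(list(name = name, task_type = task_type, modalities = modalities,
                 positive_meaning = positive_meaning, threshold = threshold),
            class = "property_task")
}

#' Assemble a property dataset
#'
#' A dataset is a view over validated records for one task: every record must
#' carry a label for `task$name` and ids must be unique.
#'
#' @param task A `property_task`.
#' @param records List of `peptide_record`s.
#' @param split Optional `split_assignment`.
#' @return A `property_dataset`.
#' @export
property_dataset <- function(task, records, split = NULL) {
  stopifnot(inherits(task, "property_task"))
  ids <- vapply(records, function(r) r$id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop("duplicate record id(s): ", paste(dup, collapse = ", "))
  for (r in records) {
    validate_record(r)
    if (!(task$name %in% names(r$labels)))
      stop("record '", r$id, "' lacks a label for task '", task$name, "'")
    if (!(r$modality %in% task$modalities))
      stop("record '", r$id, "' modality ", r$modality,
           " not accepted by task '", task$name, "'")
    if (task$task_type == "binary" &&
        !(r$labels[[task$name]] %in% c(0, 1)))
      stop("record '", r$id, "': binary label must be exactly 0 or 1")
  }
  structure(list(task = task, records = records, split = split),
            class = "property_dataset")
}

#' Summarize a property dataset
#'
#' Binary tasks: per-class counts. Regression tasks: n, min, max, mean.
#'
#' @param ds A `property_dataset`.
#' @return A named list; counts always sum to the record count.
#' @export
dataset_summary <- function(ds) {
  stopifnot(inherits(ds, "property_dataset"))
  n <- length(ds$records)
  if (n == 0) return(list(n = 0))
  y <- vapply(ds$records, function(r) r$labels[[ds$task$name]], numeric(1))
  if (ds$task$task_type == "binary") {
    list(n = n, class1 = sum(y == 1), class0 = sum(y == 0))
  } else {
    list(n = n, min = min(y), max = max(y), mean = mean(y))
  }
}

#' @export
print.property_dataset <- function(x, ...) {
  s <- dataset_summary(x)
  cat("<property_dataset> task:", x$task$name,
      "(", x$task$task_type, "),", s$n, "records\n")
  if (x$task$task_type == "binary" && s$n > 0)
    cat("  class 1:", s$class1, " class 0:", s$class0, "\n")
  invisible(x)
}

#' Dataset accessors
#'
#' Labels (for the dataset's task), ids and payloads of a
#' `property_dataset`, in record order.
#'
#' @param ds A `property_dataset`.
#' @return Numeric (labels) or character (ids, payloads) vector.
#' @export
dataset_labels <- function(ds) {
  vapply(ds$records, function(r) r$labels[[ds$task$name]], numeric(1))
}

#' @rdname dataset_labels
#' @export
dataset_ids <- function(ds) {
  vapply(ds$records, function(r) r$id, character(1))
}

#' @rdname dataset_labels
#' @export
dataset_payloads <- function(ds) {
  vapply(ds$records, function(r) r$payload, character(1))
}
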