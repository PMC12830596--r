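## CSV/JSON readers and writers. Every CSV written by the package starts with
## a schema comment line "#mitovar:<name>/<version>"; readers reject unknown
## schema versions so silently incompatible tables cannot be ingested.

.SCHEMAS <- c(fibre = "fibre-table/1", qpcr = "qpcr-plate/1",
              pyroseq = "pyroseq/1", generic = "table/1")

.writeCsvWithSchema <- function(df, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#mitovar:", schema), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.readCsvWithSchema <- function(path, schema) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#mitovar:")) {
    stop(sprintf("'%s' carries no schema line; not a table written by this package", path))
  }
  found <- sub("^#mitovar:", "", first)
  if (found != schema) {
    stop(sprintf("'%s' has schema '%s'; expected '%s'", path, found, schema))
  }
  read.csv(path, comment.char = "#", check.names = FALSE)
}

#' Read and write fibre intensity tables
#'
#' Fibre tables are CSV files with a schema header line, one row per fibre
#' cross-section and columns `fibre_id`, `patient`, `muscle`, `biopsy`,
#' `section`, `vdac1` plus one intensity column per OXPHOS protein (and
#' optionally `batch`, `label_<protein>`, `in_ground_truth_region`). On
#' ingestion, rows with non-finite or non-positive intensities are dropped
#' with a message stating the count; missing required columns raise an error.
#'
#' @param path File path.
#' @param proteins Intensity columns to validate; by default all
#'   non-identifier, non-label columns.
#' @return `readFibreTable()` returns the validated data.frame (wrap with
#'   [FibreExperiment()] as needed); `writeFibreTable()` returns the path,
#'   invisibly.
#' @export
readFibreTable <- function(path, proteins = NULL) {
  df <- .readCsvWithSchema(path, .SCHEMAS[["fibre"]])
  .assertColumns(df, c("fibre_id", "patient", "muscle", "biopsy", "section",
                       "vdac1"), "fibre table")
  if (is.null(proteins)) {
    proteins <- setdiff(names(df),
                        c("fibre_id", "patient", "muscle", "biopsy", "section",
                          "batch", "in_ground_truth_region",
                          grep("^label_", names(df), value = TRUE)))
  } else {
    proteins <- union("vdac1", proteins)
  }
  val <- as.matrix(df[, proteins, drop = FALSE])
  ok <- rowSums(!is.finite(val) | val <= 0) == 0L
  if (any(!ok)) {
    message(sprintf("dropped %d row(s) with non-finite or non-positive intensities",
                    sum(!ok)))
    df <- df[ok, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' @rdname readFibreTable
#' @param x A fibre table data.frame or a [FibreExperiment].
#' @export
writeFibreTable <- function(x, path) {
  if (is(x, "FibreExperiment")) x <- fibreTable(x)
  .writeCsvWithSchema(x, path, .SCHEMAS[["fibre"]])
}

#' Read and write polygon annotations
#'
#' Annotations are stored as JSON: a list of records with `investigator`,
#' `protein`, `scope` (section id), `category` (`"low"`/`"high"`) and
#' `vertices`, an ordered list of (VDAC1, OXPHOS) coordinate pairs.
#'
#' @param annotations Annotation list (see [generateAnnotations()]).
#' @param path File path.
#' @return `readAnnotations()` returns the annotation list;
#'   `writeAnnotations()` the path, invisibly.
#' @export
writeAnnotations <- function(annotations, path) {
  payload <- list(schema = "mitovar-annotations/1",
                  annotations = lapply(annotations, function(a) {
                    list(investigator = a$investigator, protein = a$protein,
                         scope = a$scope, category = a$category,
                         vertices = unname(apply(a$vertices, 1L, c,
                                                 simplify = FALSE)))
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$schema, "mitovar-annotations/1")) {
    stop(sprintf("'%s' is not a recognised annotation file", path))
  }
  lapply(payload$annotations, function(a) {
    v <- do.call(rbind, lapply(a$vertices, function(p) as.numeric(unlist(p))))
    colnames(v) <- c("vdac1", "oxphos")
    list(investigator = a$investigator, protein = a$protein, scope = a$scope,
         category = a$category, vertices = v)
  })
}

#' Read and write qPCR plates
#'
#' A plate is stored as one long CSV with a `role` column: `standard` rows
#' carry `copies_or_biopsy` = known copies per reaction, `sample` rows the
#' biopsy id; each row is one replicate Cq for one target.
#'
#' @param plate A [QPCRPlate].
#' @param path File path.
#' @return `readQpcrPlate()` returns a [QPCRPlate] (without generating-truth
#'   slots); `writeQpcrPlate()` the path, invisibly.
#' @export
writeQpcrPlate <- function(plate, path) {
  stopifnot(is(plate, "QPCRPlate"))
  d <- plate@dilutions
  s <- plate@samples
  df <- rbind(
    data.frame(role = "standard", target = d$target,
               copies_or_biopsy = as.character(d$copies),
               replicate = d$replicate, cq = d$cq),
    data.frame(role = "sample", target = s$target,
               copies_or_biopsy = s$biopsy,
               replicate = s$replicate, cq = s$cq))
  .writeCsvWithSchema(df, path, .SCHEMAS[["qpcr"]])
}

#' @rdname writeQpcrPlate
#' @export
readQpcrPlate <- function(path) {
  df <- .readCsvWithSchema(path, .SCHEMAS[["qpcr"]])
  .assertColumns(df, c("role", "target", "copies_or_biopsy", "replicate", "cq"),
                 "qPCR plate")
  std <- df[df$role == "standard", ]
  smp <- df[df$role == "sample", ]
  new("QPCRPlate",
      dilutions = data.frame(target = std$target,
                             copies = as.numeric(std$copies_or_biopsy),
                             replicate = std$replicate, cq = std$cq),
      samples = data.frame(biopsy = smp$copies_or_biopsy, target = smp$target,
                           replicate = smp$replicate, cq = smp$cq),
      trueCurve = data.frame(), trueMcn = numeric(0), cqNoiseSd = NA_real_)
}

#' Read and write pyrosequencing records
#'
#' One long CSV: biopsy rows (`role = "sample"`) and assay standards
#' (`role = "standard"`, biopsy column carries the nominal level).
#'
#' @param pyro List with `records` and `standards` as returned by
#'   [generatePyroseq()].
#' @param path File path.
#' @return `readPyroseq()` returns such a list; `writePyroseq()` the path,
#'   invisibly.
#' @export
writePyroseq <- function(pyro, path) {
  df <- rbind(
    data.frame(role = "sample", biopsy = pyro$records$biopsy,
               replicate = pyro$records$replicate, het = pyro$records$het),
    data.frame(role = "standard", biopsy = as.character(pyro$standards$level),
               replicate = pyro$standards$replicate, het = pyro$standards$het))
  .writeCsvWithSchema(df, path, .SCHEMAS[["pyroseq"]])
}

#' @rdname writePyroseq
#' @export
readPyroseq <- function(path) {
  df <- .readCsvWithSchema(path, .SCHEMAS[["pyroseq"]])
  .assertColumns(df, c("role", "biopsy", "replicate", "het"), "pyroseq table")
  list(records = df[df$role == "sample", c("biopsy", "replicate", "het")],
       standards = data.frame(level = as.numeric(df$biopsy[df$role == "standard"]),
                              replicate = df$replicate[df$role == "standard"],
                              het = df$het[df$role == "standard"]))
}

#' Write cohort metadata (hierarchy, positions, L-splits) as JSON
#'
#' @param cohort A [MitoCohort].
#' @param path File path.
#' @return The path, invisibly.
#' @export
writeCohortMetadata <- function(cohort, path) {
  sec <- sectionInfo(cohort)
  payload <- list(schema = "mitovar-cohort/1", sections = sec)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a pipeline configuration (JSON or YAML)
#'
#' @param path Configuration file; format chosen by extension (`.json`,
#'   `.yml`/`.yaml`).
#' @return A named list for [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs needs the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    stop("config must be .json or .yaml")
  }
}
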