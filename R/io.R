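#' Read and write vertex tables
#'
#' Vertex tables are TSV files with columns `vertex_id`, `hemisphere`, `x`,
#' `y`, `z`, `region`, `thickness`. Reading validates the contract: unique
#' vertex ids, hemisphere codes in {L, R}, strictly positive thickness, and
#' unit-norm coordinates (tolerance 1e-6); violations raise a parse error
#' naming the first offending row.
#'
#' @param x a vertex table (tibble).
#' @param path file path.
#' @return `read_vertex_table()` returns a validated tibble;
#'   `write_vertex_table()` returns `path` invisibly.
#' @export
write_vertex_table <- function(x, path) {
  validate_vertex_table(x)
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_vertex_table
#' @export
read_vertex_table <- function(path) {
  cols <- c("vertex_id", "hemisphere", "x", "y", "z", "region", "thickness")
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(cols, header)
  if (length(missing)) {
    stop_parse(sprintf("vertex table %s lacks columns: %s",
                       path, paste(missing, collapse = ", ")))
  }
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      vertex_id = readr::col_integer(),
      hemisphere = readr::col_character(),
      x = readr::col_double(), y = readr::col_double(),
      z = readr::col_double(),
      region = readr::col_character(),
      thickness = readr::col_double()
    )
  )
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop_parse(sprintf("vertex table %s lacks columns: %s",
                       path, paste(missing, collapse = ", ")))
  }
  validate_vertex_table(x[cols], path = path)
  x[cols]
}

validate_vertex_table <- function(x, path = "<in-memory>") {
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i)) {
      stop_parse(sprintf("vertex table %s: %s at row %d", path, what, i[1]))
    }
  }
  bad_row(is.na(x$thickness) | x$thickness <= 0, "non-positive thickness")
  bad_row(!x$hemisphere %in% c("L", "R"), "unknown hemisphere code")
  bad_row(duplicated(x$vertex_id), "duplicate vertex id")
  nrm <- sqrt(x$x^2 + x$y^2 + x$z^2)
  bad_row(abs(nrm - 1) > 1e-6, "coordinates not unit-norm")
  invisible(x)
}

#' Read, write, and filter cohort manifests
#'
#' Manifests are CSV files with columns `subject_id`, `gender`, `age`,
#' `handedness`, `family_id`. `filter_cohort()` applies the cohort selection
#' rule: keep subjects whose handedness score is at least `handedness_min`,
#' then exactly one subject per family (the first in subject-id order).
#'
#' @param x a manifest tibble.
#' @param path file path.
#' @param manifest a manifest tibble.
#' @param handedness_min minimum handedness score (default 50).
#' @return filtered / read manifest tibble.
#' @export
write_cohort_manifest <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_cohort_manifest
#' @export
read_cohort_manifest <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      gender = readr::col_character(),
      age = readr::col_double(),
      handedness = readr::col_double(),
      family_id = readr::col_character()
    )
  )
  if (anyDuplicated(x$subject_id)) {
    stop_parse(sprintf("manifest %s: duplicate subject ids", path))
  }
  x
}

#' @rdname write_cohort_manifest
#' @export
filter_cohort <- function(manifest, handedness_min = 50) {
  kept <- manifest[!is.na(manifest$handedness) &
                     manifest$handedness >= handedness_min, , drop = FALSE]
  kept <- kept[order(kept$subject_id), , drop = FALSE]
  kept <- kept[!duplicated(kept$family_id), , drop = FALSE]
  tibble::as_tibble(kept)
}

#' Square matrix artifacts (similarity weights and binarized networks)
#'
#' A matrix artifact couples a symmetric, zero-diagonal square matrix with
#' its provenance: subject, hemisphere, kind (`weights` or `binary`), the
#' sparsity level for binary matrices, and ordered node labels. On disk it is
#' a dense TSV preceded by `#key: value` metadata lines, so a 256 x 256
#' network stays human-inspectable and diff-able.
#'
#' @param values square numeric matrix.
#' @param subject_id,hemisphere,kind,sparsity,node_labels metadata fields;
#'   `sparsity` must be `NA` for weight matrices and a fraction for binary
#'   ones.
#' @param artifact a `hemimorph_matrix_artifact`.
#' @param path file path.
#' @return `matrix_artifact()` and `read_matrix_artifact()` return the
#'   validated artifact; `write_matrix_artifact()` returns `path` invisibly.
#' @export
matrix_artifact <- function(values, subject_id, hemisphere,
                            kind = c("weights", "binary"),
                            sparsity = NA_real_, node_labels = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop_input("matrix must be square")
  if (is.null(node_labels)) node_labels <- as.character(seq_len(nrow(values)))
  if (length(node_labels) != nrow(values)) {
    stop_input("node label count must equal matrix dimension")
  }
  if (max(abs(values - t(values))) > 1e-10) {
    stop_input("matrix asymmetric beyond 1e-10")
  }
  if (any(diag(values) != 0)) stop_input("diagonal must be zero")
  if (kind == "binary") {
    if (!all(values %in% c(0, 1))) {
      stop_input("binary artifact contains values other than 0/1")
    }
    if (!is_number(sparsity) || sparsity <= 0 || sparsity >= 1) {
      stop_input("binary artifact requires a sparsity fraction in (0, 1)")
    }
  } else {
    sparsity <- NA_real_
  }
  structure(
    list(subject_id = subject_id, hemisphere = hemisphere, kind = kind,
         sparsity = sparsity, node_labels = as.character(node_labels),
         values = unname(values)),
    class = "hemimorph_matrix_artifact"
  )
}

#' @rdname matrix_artifact
#' @export
write_matrix_artifact <- function(artifact, path) {
  stopifnot(inherits(artifact, "hemimorph_matrix_artifact"))
  hdr <- c(
    sprintf("#subject_id: %s", artifact$subject_id),
    sprintf("#hemisphere: %s", artifact$hemisphere),
    sprintf("#kind: %s", artifact$kind),
    sprintf("#sparsity: %s",
            ifelse(is.na(artifact$sparsity), "NA",
                   format(artifact$sparsity, digits = 15))),
    sprintf("#node_labels: %s", paste(artifact$node_labels, collapse = "\t"))
  )
  body <- apply(artifact$values, 1, function(r) {
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname matrix_artifact
#' @export
read_matrix_artifact <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  meta <- list()
  for (h in lines[is_hdr]) {
    kv <- sub("^#([^:]+): ?", "\\1\x01", h)
    parts <- strsplit(kv, "\x01", fixed = TRUE)[[1]]
    meta[[parts[1]]] <- if (length(parts) > 1) parts[2] else ""
  }
  need <- c("subject_id", "hemisphere", "kind", "sparsity", "node_labels")
  if (!all(need %in% names(meta))) {
    stop_parse(sprintf("matrix artifact %s: incomplete metadata header", path))
  }
  values <- do.call(rbind, lapply(strsplit(lines[!is_hdr], "\t"), as.numeric))
  matrix_artifact(
    values,
    subject_id = meta$subject_id,
    hemisphere = meta$hemisphere,
    kind = meta$kind,
    sparsity = suppressWarnings(as.numeric(meta$sparsity)),
    node_labels = strsplit(meta$node_labels, "\t", fixed = TRUE)[[1]]
  )
}
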