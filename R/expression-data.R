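#' Construct a two-condition expression matrix
#'
#' `deg_matrix()` wraps a numeric genes-by-samples matrix of log-scale
#' expression intensities together with an optional two-condition design.
#' Gene identifiers may repeat (probe sets often map to the same symbol);
#' sample identifiers must be unique. All values must be finite: missing
#' values are rejected rather than imputed, since they would silently
#' corrupt the per-gene summary statistics downstream.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are used as gene and sample identifiers unless `gene_ids`
#'   or `sample_ids` are supplied.
#' @param design optional group assignment: a character vector of condition
#'   labels named by sample identifier, with exactly two distinct labels
#'   (see [group_design()]).
#' @param gene_ids,sample_ids optional identifier vectors overriding dimnames.
#' @param log_scale logical; whether `values` are already on the log scale.
#'   Feature computation requires log-scale data.
#' @return an object of class `deg_matrix`.
#' @seealso [read_expression_matrix()], [log_transform()], [compute_features()]
#' @export
#' @examples
#' m <- matrix(rnorm(12, 7), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' x <- deg_matrix(m, design = group_design(c(s1 = "ctl", s2 = "ctl",
#'                                            s3 = "trt", s4 = "trt")))
#' x
deg_matrix <- function(values, design = NULL, gene_ids = NULL,
                       sample_ids = NULL, log_scale = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  gene_ids <- gene_ids %||% rownames(values) %||% paste0("gene_", seq_len(nrow(values)))
  sample_ids <- sample_ids %||% colnames(values) %||% paste0("sample_", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) < 1L) abort("matrix must contain at least one gene row.")
  if (ncol(values) < 2L) abort("matrix must contain at least two sample columns.")
  if (length(gene_ids) != nrow(values)) {
    abort("`gene_ids` length must equal the number of rows.")
  }
  if (length(sample_ids) != ncol(values)) {
    abort("`sample_ids` length must equal the number of columns.")
  }
  if (anyDuplicated(sample_ids)) {
    abort(paste0("duplicate sample ID: ",
                 sample_ids[duplicated(sample_ids)][1L]))
  }
  bad <- which(!is.finite(values))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(values)) + 1L
    abort(sprintf("non-finite value at gene '%s' (row %d), sample '%s' (column %d).",
                  gene_ids[i], i, sample_ids[j], j))
  }
  dimnames(values) <- NULL
  x <- structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         design = NULL, log_scale = isTRUE(log_scale)),
    class = "deg_matrix"
  )
  if (!is.null(design)) x <- set_design(x, design)
  x
}

#' Create or attach a two-condition group design
#'
#' A group design maps every sample to one of two conditions, internally
#' labelled `A` and `B`. The first label encountered becomes condition `A`
#' unless `a_label` names it explicitly.
#'
#' @param labels character vector of condition labels named by sample ID,
#'   with exactly two distinct values.
#' @param a_label optional: which label is condition A.
#' @return a named character vector of `"A"`/`"B"` with attributes
#'   `label_a`/`label_b` recording the original names.
#' @export
group_design <- function(labels, a_label = NULL) {
  if (is.null(names(labels)) || any(!nzchar(names(labels)))) {
    abort("`labels` must be named by sample ID.")
  }
  labels <- vapply(labels, as.character, character(1))
  lev <- unique(labels)
  if (length(lev) != 2L) {
    abort(sprintf("expected exactly 2 distinct condition labels, found %d (%s).",
                  length(lev), paste(lev, collapse = ", ")))
  }
  if (!is.null(a_label)) {
    if (!a_label %in% lev) abort(sprintf("`a_label` '%s' is not a label in the design.", a_label))
    lev <- c(a_label, setdiff(lev, a_label))
  }
  out <- ifelse(labels == lev[1L], "A", "B")
  names(out) <- names(labels)
  attr(out, "label_a") <- lev[1L]
  attr(out, "label_b") <- lev[2L]
  out
}

#' @rdname group_design
#' @param x a `deg_matrix`.
#' @param design a design from [group_design()] or a plain named label vector.
#' @export
set_design <- function(x, design) {
  stopifnot(inherits(x, "deg_matrix"))
  if (is.null(attr(design, "label_a"))) design <- group_design(design)
  missing <- setdiff(x$sample_ids, names(design))
  if (length(missing)) {
    abort(paste0("no condition label for sample(s): ", paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(design), x$sample_ids)
  if (length(unknown)) {
    abort(paste0("label(s) for unknown sample(s): ", paste(unknown, collapse = ", ")))
  }
  design <- design[x$sample_ids]
  if (sum(design == "A") < 1L || sum(design == "B") < 1L) {
    abort("each condition must contain at least one sample.")
  }
  x$design <- design
  x
}

samples_in <- function(x, condition) {
  if (is.null(x$design)) abort("matrix has no group design; see `set_design()`.")
  which(x$design == condition)
}

#' @export
print.deg_matrix <- function(x, ...) {
  cat(sprintf("<deg_matrix> %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log_scale) "log" else "linear"))
  if (!is.null(x$design)) {
    cat(sprintf("  design: %d A ('%s') vs %d B ('%s')\n",
                sum(x$design == "A"), attr(x$design, "label_a") %||% "A",
                sum(x$design == "B"), attr(x$design, "label_b") %||% "B"))
  } else {
    cat("  design: none\n")
  }
  invisible(x)
}

#' @export
dim.deg_matrix <- function(x) dim(x$values)

#' Read a tab-separated expression matrix
#'
#' Reads a UTF-8, tab-separated text file with a header row of sample IDs and
#' one gene per row; the gene identifier is taken from `gene_id_column`
#' (the first column by default). Every expression cell must parse as a
#' finite number: a missing, empty or non-numeric cell is an error naming the
#' offending gene row and sample column. Input row order is preserved.
#'
#' @param path file path.
#' @param gene_id_column column name or index holding gene identifiers.
#' @param log_scale whether the stored intensities are already log scale.
#' @return a `deg_matrix` without a design; attach one with [set_design()].
#' @export
read_expression_matrix <- function(path, gene_id_column = 1L, log_scale = TRUE) {
  header <- strsplit(readr::read_lines(path, n_max = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    abort(paste0("duplicate sample ID in header: ",
                 header[duplicated(header)][1L]))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, na = character())
  prob <- readr::problems(df)
  if (nrow(prob)) {
    abort(sprintf("malformed TSV at line %d: %s", prob$row[1L] + 1L, prob$expected[1L]))
  }
  if (is.numeric(gene_id_column)) gene_id_column <- names(df)[gene_id_column]
  if (!gene_id_column %in% names(df)) {
    abort(sprintf("gene ID column '%s' not found in header.", gene_id_column))
  }
  gene_ids <- df[[gene_id_column]]
  sample_ids <- setdiff(names(df), gene_id_column)
  if (anyDuplicated(sample_ids)) {
    abort(paste0("duplicate sample ID in header: ",
                 sample_ids[duplicated(sample_ids)][1L]))
  }
  if (length(sample_ids) < 2L) abort("matrix must contain at least two sample columns.")
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- df[[sample_ids[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !nzchar(trimws(col)))
    if (length(bad)) {
      abort(sprintf(
        "missing or non-numeric value '%s' at gene '%s' (row %d), sample '%s'.",
        col[bad[1L]], gene_ids[bad[1L]], bad[1L], sample_ids[j]))
    }
    vals[, j] <- num
  }
  deg_matrix(vals, gene_ids = gene_ids, sample_ids = sample_ids,
             log_scale = log_scale)
}

#' Write an expression matrix as TSV
#'
#' Emits a tab-separated file with a `gene_id` column and one column per
#' sample, values formatted to 6 significant digits.
#'
#' @param x a `deg_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "deg_matrix"))
  df <- as.data.frame(signif(x$values, 6L))
  names(df) <- x$sample_ids
  df <- cbind(gene_id = x$gene_ids, df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a two-column sample-to-condition assignment
#'
#' The file has one row per sample: sample ID, then condition label,
#' tab-separated, no header. Exactly two distinct labels must appear and
#' every sample in `sample_ids` must be labelled exactly once.
#'
#' @param path file path.
#' @param sample_ids sample identifiers the design must cover (typically
#'   `x$sample_ids`).
#' @param a_label optional explicit name of condition A; by default the first
#'   label encountered in the file maps to A.
#' @return a design vector as from [group_design()].
#' @export
read_group_design <- function(path, sample_ids, a_label = NULL) {
  df <- readr::read_tsv(path, col_names = c("sample_id", "label"),
                        col_types = "cc", progress = FALSE)
  if (anyDuplicated(df$sample_id)) {
    abort(paste0("sample labelled more than once: ",
                 df$sample_id[duplicated(df$sample_id)][1L]))
  }
  labels <- df$label
  names(labels) <- df$sample_id
  unknown <- setdiff(df$sample_id, sample_ids)
  if (length(unknown)) {
    abort(paste0("label(s) for sample(s) not in the matrix: ",
                 paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(sample_ids, df$sample_id)
  if (length(missing)) {
    abort(paste0("no condition label for sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  group_design(labels, a_label = a_label)
}

#' Read a truth set of known true DEG identifiers
#'
#' One identifier per line; blank lines are ignored.
#'
#' @param path file path.
#' @return character vector of gene identifiers.
#' @export
read_truth_set <- function(path) {
  ids <- readr::read_lines(path, progress = FALSE)
  ids <- trimws(ids)
  unique(ids[nzchar(ids)])
}

#' Log-transform a linear-scale matrix
#'
#' Replaces every intensity by `log(max(value, floor), base)`. The floor
#' guards zero or negative intensities that would otherwise map to
#' non-finite values.
#'
#' @param x a `deg_matrix` holding linear-scale intensities.
#' @param base logarithm base (default 2, the field convention).
#' @param floor positive lower clamp applied before the logarithm.
#' @return the transformed `deg_matrix`, marked log-scale.
#' @export
log_transform <- function(x, base = 2, floor = 1) {
  stopifnot(inherits(x, "deg_matrix"))
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0) {
    abort("`floor` must be a single positive number.")
  }
  if (x$log_scale) {
    warn("matrix is already marked log-scale; transforming anyway.")
  }
  x$values <- log(pmax(x$values, floor), base = base)
  x$log_scale <- TRUE
  x
}

#' Subsample columns within each condition
#'
#' Draws `n_a` condition-A samples and `n_b` condition-B samples uniformly
#' without replacement, reproducibly for a fixed `seed`. Gene rows are
#' unchanged and condition labels are never mixed. This emulates the
#' small-sample regime (2x2, 3x3, 4x4 designs) common in historical
#' microarray series.
#'
#' @param x a `deg_matrix` with a design.
#' @param n_a,n_b number of samples to keep per condition.
#' @param seed integer seed controlling the draw.
#' @return a `deg_matrix` restricted to the selected columns.
#' @export
subsample_columns <- function(x, n_a, n_b, seed) {
  stopifnot(inherits(x, "deg_matrix"))
  a_idx <- samples_in(x, "A")
  b_idx <- samples_in(x, "B")
  if (n_a < 1L || n_a > length(a_idx)) {
    abort(sprintf("`n_a` must be in 1..%d (samples in condition A).", length(a_idx)))
  }
  if (n_b < 1L || n_b > length(b_idx)) {
    abort(sprintf("`n_b` must be in 1..%d (samples in condition B).", length(b_idx)))
  }
  keep <- withr::with_seed(seed, {
    c(a_idx[sample.int(length(a_idx), n_a)],
      b_idx[sample.int(length(b_idx), n_b)])
  })
  keep <- sort(keep)
  out <- deg_matrix(x$values[, keep, drop = FALSE],
                    gene_ids = x$gene_ids,
                    sample_ids = x$sample_ids[keep],
                    log_scale = x$log_scale)
  set_design(out, x$design[keep])
}
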