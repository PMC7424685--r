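GATE_OPS <- c("<", "<=", ">", ">=")

#' Construct a linear gate
#'
#' A linear gate is a named conjunction of threshold clauses over feature
#' table columns; an object passes iff every clause holds. Objects with an
#' absent (`NA`) feature in any clause fail that gate.
#'
#' @param name class name the gate assigns.
#' @param clauses data frame with columns `feature` (a dotted
#'   `channel.feature` column name), `op` (one of `<`, `<=`, `>`, `>=`)
#'   and `value` (finite numeric threshold).
#' @return An object of class `evg_gate`.
#' @export
linear_gate <- function(name, clauses) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  clauses <- as.data.frame(clauses, stringsAsFactors = FALSE)
  if (nrow(clauses) < 1L) stop("gate '", name, "' must have at least one clause")
  if (!all(c("feature", "op", "value") %in% names(clauses))) {
    stop("clauses need columns: feature, op, value")
  }
  clauses <- clauses[, c("feature", "op", "value")]
  if (!all(clauses$op %in% GATE_OPS)) {
    stop("gate '", name, "': comparator must be one of ", paste(GATE_OPS, collapse = " "))
  }
  if (!all(is.finite(clauses$value))) stop("gate '", name, "': thresholds must be finite")
  bad <- setdiff(clauses$feature, gate_feature_vocabulary())
  if (length(bad) > 0L) {
    stop("gate '", name, "': unknown feature(s) ", paste(bad, collapse = ", "),
         "; valid features are: ", paste(gate_feature_vocabulary(), collapse = ", "))
  }
  structure(list(name = name, clauses = clauses), class = "evg_gate")
}

#' Feature names a gate clause may reference
#' @return Character vector of valid dotted feature names.
#' @export
gate_feature_vocabulary <- function() {
  setdiff(feature_columns(),
          c("frame_id", "object_id", "n_pixels", "centroid_row", "centroid_col"))
}

#' Construct a gate set
#'
#' @param gates list of [linear_gate()]s with unique names, in priority
#'   order (relevant under the `first_match` policy).
#' @param policy `"first_match"` assigns the first passing gate;
#'   `"error_on_multimatch"` raises a diagnostic if any object satisfies
#'   more than one gate (useful for validating gate libraries).
#' @return An object of class `evg_gate_set`.
#' @export
gate_set <- function(gates, policy = c("first_match", "error_on_multimatch")) {
  policy <- match.arg(policy)
  stopifnot(is.list(gates), length(gates) >= 1L)
  if (!all(vapply(gates, inherits, logical(1), "evg_gate"))) {
    stop("all elements must be evg_gate objects")
  }
  nms <- vapply(gates, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate class name(s): ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  structure(list(gates = setNames(gates, nms), policy = policy),
            class = "evg_gate_set")
}

#' @export
print.evg_gate_set <- function(x, ...) {
  cat("<evg_gate_set>", length(x$gates), "gates, policy:", x$policy, "\n")
  for (g in x$gates) {
    cat("  ", g$name, ": ",
        paste(sprintf("%s %s %g", g$clauses$feature, g$clauses$op, g$clauses$value),
              collapse = " & "), "\n", sep = "")
  }
  invisible(x)
}

#' The default six-class CTC/tdEV gate library
#'
#' Implements the qualitative class definitions: a CTC is a nucleated
#' (DNA-positive), CD45-negative object larger than 4 um expressing CK
#' and/or HER2 with its CK/HER2 signal overlapping the nucleus; a tdEV is
#' an anucleate, CD45-negative CK and/or HER2-positive object of 1-14 um.
#' Each compartment is split into CK+HER2-, CK-HER2+ and CK+HER2+
#' phenotypes. Thresholds are calibrated against the synthetic imaging
#' model's background (marker positivity well above background plus noise)
#' and are fully user-overridable; the gate engine, not the constants, is
#' the contract. The six gates are pairwise disjoint by construction (the
#' DNA axis separates CTC from tdEV, the CK/HER2 axes the phenotypes).
#'
#' @param dna_pos DNA mean-intensity threshold for "nucleated".
#' @param marker_pos CK / HER2 mean-intensity positivity threshold.
#' @param cd45_max CD45 mean-intensity exclusion threshold.
#' @param overlap_min minimum CK/HER2-with-DNA overlap fraction for CTCs.
#' @param ctc_min_diam_um minimum CTC equivalent diameter (strict `>`), um.
#' @param tdev_diam_um inclusive tdEV equivalent-diameter range, um.
#' @return An `evg_gate_set` with the six tumor classes (CTC gates first).
#' @export
default_gate_set <- function(dna_pos = 120, marker_pos = 150, cd45_max = 120,
                             overlap_min = 0.5, ctc_min_diam_um = 4,
                             tdev_diam_um = c(1, 14)) {
  cl <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(feature = m[, 1], op = m[, 2], value = as.numeric(m[, 3]),
               stringsAsFactors = FALSE)
  }
  ctc_base <- function(extra) rbind(
    cl("DNA.mean_int", ">=", dna_pos,
       "CD45.mean_int", "<", cd45_max,
       "object.eq_diameter_um", ">", ctc_min_diam_um),
    extra
  )
  tdev_base <- function(extra) rbind(
    cl("DNA.mean_int", "<", dna_pos,
       "CD45.mean_int", "<", cd45_max,
       "object.eq_diameter_um", ">=", tdev_diam_um[1],
       "object.eq_diameter_um", "<=", tdev_diam_um[2]),
    extra
  )
  gate_set(list(
    linear_gate("ctc_ck_her2neg", ctc_base(cl(
      "CK.mean_int", ">=", marker_pos, "HER2.mean_int", "<", marker_pos,
      "CK.dna_overlap", ">=", overlap_min))),
    linear_gate("ctc_ckneg_her2", ctc_base(cl(
      "CK.mean_int", "<", marker_pos, "HER2.mean_int", ">=", marker_pos,
      "HER2.dna_overlap", ">=", overlap_min))),
    linear_gate("ctc_ck_her2", ctc_base(cl(
      "CK.mean_int", ">=", marker_pos, "HER2.mean_int", ">=", marker_pos,
      "CK.dna_overlap", ">=", overlap_min))),
    linear_gate("tdev_ck_her2neg", tdev_base(cl(
      "CK.mean_int", ">=", marker_pos, "HER2.mean_int", "<", marker_pos))),
    linear_gate("tdev_ckneg_her2", tdev_base(cl(
      "CK.mean_int", "<", marker_pos, "HER2.mean_int", ">=", marker_pos))),
    linear_gate("tdev_ck_her2", tdev_base(cl(
      "CK.mean_int", ">=", marker_pos, "HER2.mean_int", ">=", marker_pos)))
  ))
}

#' Serialize a gate set to its configuration text
#'
#' @param gates an `evg_gate_set`.
#' @return Character vector of configuration lines; `parse_gates()` of the
#'   result reproduces the gate set exactly.
#' @export
serialize_gates <- function(gates) {
  stopifnot(inherits(gates, "evg_gate_set"))
  out <- c(paste0("policy: ", gates$policy), "")
  for (g in gates$gates) {
    out <- c(out, paste0("class ", g$name),
             sprintf("  %s %s %s", g$clauses$feature, g$clauses$op,
                     format(g$clauses$value, digits = 15, trim = TRUE,
                            scientific = FALSE)),
             "")
  }
  out
}

#' Parse a gate configuration
#'
#' The grammar is line-based: an optional `policy:` line, then one block
#' per class starting with `class <name>` followed by indented clause
#' lines `channel.feature comparator value`, e.g.
#' `DNA.mean_int >= 120`. `#` starts a comment. Unknown feature names,
#' malformed clauses and duplicate class names are rejected with the
#' offending line number.
#'
#' @param text character vector of configuration lines, or `NULL`.
#' @param path path to a configuration file (used when `text` is `NULL`).
#' @return An `evg_gate_set`.
#' @export
parse_gates <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("either text or path must be given")
    text <- readLines(path, warn = FALSE)
  }
  lines <- sub("#.*$", "", text)
  policy <- "first_match"
  gates <- list()
  cur_name <- NULL
  cur_clauses <- NULL
  flush <- function() {
    if (is.null(cur_name)) return()
    if (is.null(cur_clauses) || nrow(cur_clauses) == 0L) {
      stop("gate '", cur_name, "' has no clauses")
    }
    if (cur_name %in% vapply(gates, `[[`, "", "name")) {
      stop("duplicate class name: ", cur_name)
    }
    gates[[length(gates) + 1L]] <<- linear_gate(cur_name, cur_clauses)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^policy:", ln)) {
      policy <- trimws(sub("^policy:", "", ln))
      next
    }
    if (grepl("^class\\s+", ln)) {
      flush()
      cur_name <- trimws(sub("^class\\s+", "", ln))
      cur_clauses <- data.frame(feature = character(0), op = character(0),
                                value = numeric(0), stringsAsFactors = FALSE)
      next
    }
    toks <- strsplit(ln, "\\s+")[[1]]
    if (length(toks) < 3L || is.null(cur_name)) {
      stop("malformed gate configuration at line ", i, ": '", trimws(text[i]), "'")
    }
    val <- suppressWarnings(as.numeric(toks[3]))
    if (!toks[2] %in% GATE_OPS || is.na(val)) {
      stop("malformed clause at line ", i, ": '", trimws(text[i]), "'")
    }
    cur_clauses <- rbind(cur_clauses,
                         data.frame(feature = toks[1], op = toks[2], value = val,
                                    stringsAsFactors = FALSE))
  }
  flush()
  if (length(gates) == 0L) stop("gate configuration defines no classes")
  gate_set(gates, policy = policy)
}

#' Apply one gate to a feature table
#'
#' @param gate an `evg_gate`.
#' @param table a feature table containing the gate's feature columns.
#' @return Logical vector, one element per row: `TRUE` iff all clauses
#'   hold; rows with `NA` in any clause feature yield `FALSE`.
#' @export
apply_gate <- function(gate, table) {
  stopifnot(inherits(gate, "evg_gate"), is.data.frame(table))
  missing_col <- setdiff(gate$clauses$feature, names(table))
  if (length(missing_col) > 0L) {
    stop("table lacks gate feature column(s): ", paste(missing_col, collapse = ", "))
  }
  pass <- rep(TRUE, nrow(table))
  for (j in seq_len(nrow(gate$clauses))) {
    v <- table[[gate$clauses$feature[j]]]
    ok <- switch(gate$clauses$op[j],
                 "<" = v < gate$clauses$value[j],
                 "<=" = v <= gate$clauses$value[j],
                 ">" = v > gate$clauses$value[j],
                 ">=" = v >= gate$clauses$value[j])
    ok[is.na(ok)] <- FALSE
    pass <- pass & ok
  }
  pass
}

#' Classify a feature table with a gate set
#'
#' @param table feature table as returned by [detect()].
#' @param gates an `evg_gate_set` (default: [default_gate_set()]).
#' @return The table with an added `class` column; objects matching no
#'   gate are labeled `"unclassified"`. Under the `error_on_multimatch`
#'   policy an object satisfying two gates raises an error naming both.
#' @export
classify <- function(table, gates = default_gate_set()) {
  stopifnot(is.data.frame(table), inherits(gates, "evg_gate_set"))
  n <- nrow(table)
  label <- rep(EVG_UNCLASSIFIED, n)
  if (n > 0L) {
    pass <- vapply(gates$gates, apply_gate, logical(n), table = table)
    pass <- matrix(pass, nrow = n,
                   dimnames = list(NULL, names(gates$gates)))
    if (gates$policy == "error_on_multimatch") {
      multi <- which(rowSums(pass) > 1L)
      if (length(multi) > 0L) {
        i <- multi[1]
        stop("object in row ", i, " matches multiple gates: ",
             paste(colnames(pass)[pass[i, ]], collapse = ", "))
      }
    }
    hit <- apply(pass, 1L, function(p) {
      w <- which(p)
      if (length(w) == 0L) EVG_UNCLASSIFIED else colnames(pass)[w[1]]
    })
    label <- unname(hit)
  }
  table$class <- label
  table
}

#' Count objects per class
#'
#' @param classified a table with a `class` column, as from [classify()].
#' @param gates gate set defining the class universe (so zero counts are
#'   reported for absent classes).
#' @param sample_id optional sample identifier attached to the result.
#' @return Named integer vector over all gate classes plus
#'   `"unclassified"`; the counts sum to `nrow(classified)`.
#' @export
count_classes <- function(classified, gates = default_gate_set(), sample_id = NULL) {
  stopifnot(is.data.frame(classified), "class" %in% names(classified))
  universe <- c(names(gates$gates), EVG_UNCLASSIFIED)
  extra <- setdiff(unique(classified$class), universe)
  if (length(extra) > 0L) universe <- c(universe, extra)
  tab <- table(factor(classified$class, levels = universe))
  out <- setNames(as.integer(tab), universe)
  if (!is.null(sample_id)) attr(out, "sample_id") <- sample_id
  out
}
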