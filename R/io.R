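# Readers and writers for the formats the pipeline touches: a PAUP-style
# NEXUS character-matrix dialect, Newick trees, and CSV measurement/angle
# tables. NEXUS and Newick parsing is delegated to ape; this layer adds the
# validation and error reporting the pipeline contracts require.

#' Character-taxon matrix
#'
#' Discrete morphological scorings for a set of taxa. Cells hold a single
#' state symbol, the missing symbol `?`, the gap symbol `-`, or a polymorphic
#' set written `"0/1"`.
#'
#' @param taxon_names unique taxon labels.
#' @param cells character matrix (taxa x characters) of scorings.
#' @param symbols ordered state alphabet (single characters).
#' @param missing_char,gap_char the missing and gap symbols.
#' @return an object of class `character_matrix`.
#' @export
character_matrix <- function(taxon_names, cells,
                             symbols = sort(unique(unlist(strsplit(
                               cells[!cells %in% c("?", "-")], "/")))),
                             missing_char = "?", gap_char = "-") {
  cells <- as.matrix(cells)
  dimnames(cells) <- list(as.character(taxon_names), NULL)
  if (anyDuplicated(taxon_names))
    stopf("duplicate taxon label: %s",
          taxon_names[duplicated(taxon_names)][1])
  if (length(taxon_names) < 2) stopf("a matrix needs at least 2 taxa")
  if (nrow(cells) != length(taxon_names))
    stopf("cells has %d rows for %d taxa", nrow(cells), length(taxon_names))
  obj <- structure(
    list(taxon_names = as.character(taxon_names), cells = cells,
         symbols = as.character(symbols), missing_char = missing_char,
         gap_char = gap_char, n_taxa = length(taxon_names),
         n_chars = ncol(cells)),
    class = "character_matrix"
  )
  validate_character_matrix(obj)
  obj
}

validate_character_matrix <- function(x) {
  bad <- which(!vapply(seq_len(x$n_taxa), function(i) {
    all(vapply(x$cells[i, ], function(cell) {
      if (cell %in% c(x$missing_char, x$gap_char)) return(TRUE)
      all(strsplit(cell, "/")[[1]] %in% x$symbols)
    }, TRUE))
  }, TRUE))
  if (length(bad)) {
    i <- bad[1]
    j <- which(!vapply(x$cells[i, ], function(cell)
      cell %in% c(x$missing_char, x$gap_char) ||
        all(strsplit(cell, "/")[[1]] %in% x$symbols), TRUE))[1]
    stopf("undeclared state symbol '%s' at taxon '%s', character %d",
          x$cells[i, j], x$taxon_names[i], j)
  }
  invisible(x)
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character matrix: %d taxa x %d characters, symbols {%s}\n",
              x$n_taxa, x$n_chars, paste(x$symbols, collapse = "")))
  invisible(x)
}

#' Read a PAUP-style NEXUS character matrix
#'
#' Supports DATA/CHARACTERS blocks with DIMENSIONS, FORMAT (MISSING, GAP,
#' SYMBOLS) and MATRIX commands, interleaved or not; polymorphisms written
#' `{01}` or `(01)` are parsed as state sets. TREES and ASSUMPTIONS blocks
#' are ignored with a warning. Declared dimensions, the symbol alphabet and
#' taxon-label uniqueness are all validated, with positions reported on
#' failure.
#'
#' @param x path to a NEXUS file, or the document text itself (recognized by
#'   embedded newlines).
#' @return a [character_matrix()].
#' @export
read_nexus <- function(x) {
  path <- x
  if (length(x) > 1 || grepl("\n", x)) {
    path <- tempfile(fileext = ".nex")
    on.exit(unlink(path))
    writeLines(if (length(x) > 1) x else strsplit(x, "\n")[[1]], path)
  }
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || !grepl("^#NEXUS", txt[1], ignore.case = TRUE))
    stopf("not a NEXUS document (missing #NEXUS header)")
  flat <- paste(txt, collapse = "\n")

  for (blk in c("TREES", "ASSUMPTIONS"))
    if (grepl(paste0("BEGIN\\s+", blk), flat, ignore.case = TRUE))
      warning(blk, " block present; ignored", call. = FALSE)

  dim_m <- regmatches(flat, regexpr(
    "DIMENSIONS[^;]*;", flat, ignore.case = TRUE))
  if (!length(dim_m)) stopf("no DIMENSIONS command found")
  get_num <- function(key, from) {
    m <- regmatches(from, regexpr(paste0(key, "\\s*=\\s*[0-9]+"), from,
                                  ignore.case = TRUE))
    if (!length(m)) return(NA_integer_)
    as.integer(sub(".*=\\s*", "", m))
  }
  ntax <- get_num("NTAX", dim_m[1])
  nchar_decl <- get_num("NCHAR", dim_m[1])
  if (is.na(ntax) || is.na(nchar_decl))
    stopf("DIMENSIONS must declare NTAX and NCHAR")

  fmt <- regmatches(flat, regexpr("FORMAT[^;]*;", flat, ignore.case = TRUE))
  get_chr <- function(key, from, default) {
    m <- regmatches(from, regexpr(
      paste0(key, "\\s*=\\s*\\S"), from, ignore.case = TRUE))
    if (!length(m)) return(default)
    sub(paste0("(?i)", key, "\\s*=\\s*"), "", m, perl = TRUE)
  }
  missing_char <- "?"; gap_char <- "-"; symbols <- NULL
  if (length(fmt)) {
    missing_char <- get_chr("MISSING", fmt[1], "?")
    gap_char <- get_chr("GAP", fmt[1], "-")
    sm <- regmatches(fmt[1], regexpr('SYMBOLS\\s*=\\s*"[^"]*"', fmt[1],
                                     ignore.case = TRUE))
    if (length(sm)) {
      sym_str <- gsub('.*"([^"]*)".*', "\\1", sm)
      symbols <- setdiff(strsplit(sym_str, "")[[1]], " ")
    }
  }

  # pre-scan the MATRIX block for duplicate taxon labels (position-aware);
  # ape collapses interleaves, so count first occurrences only
  mat_start <- grep("^\\s*MATRIX\\s*$", txt, ignore.case = TRUE)[1]
  if (!is.na(mat_start)) {
    body <- txt[(mat_start + 1):length(txt)]
    end <- grep(";", body, fixed = TRUE)[1]
    if (!is.na(end)) body <- body[seq_len(end - 1)]
    labs <- sub("^\\s*('[^']*'|\\S+).*$", "\\1", body[nzchar(trimws(body))])
    first_block <- labs[seq_len(min(length(labs), ntax))]
    if (anyDuplicated(first_block))
      stopf("duplicate taxon '%s' in MATRIX (row %d)",
            first_block[duplicated(first_block)][1],
            which(duplicated(first_block))[1])
    n_seen <- length(unique(labs))
    if (n_seen != ntax)
      stopf("declared NTAX=%d but MATRIX has %d taxa", ntax, n_seen)
  }

  parsed <- tryCatch(ape::read.nexus.data(path), error = function(e)
    stopf("NEXUS matrix could not be parsed (%s); check that every row has NCHAR=%d scorings",
          conditionMessage(e), nchar_decl))

  if (length(parsed) != ntax)
    stopf("declared NTAX=%d but MATRIX has %d taxa", ntax, length(parsed))
  lens <- vapply(parsed, length, 0L)
  if (any(lens != nchar_decl))
    stopf("taxon '%s' has %d scorings, declared NCHAR=%d",
          names(parsed)[lens != nchar_decl][1],
          lens[lens != nchar_decl][1], nchar_decl)

  cells <- do.call(rbind, parsed)
  # ape reports its own missing symbol as "?" already; normalize declared ones
  if (missing_char != "?") cells[cells == missing_char] <- "?"
  if (gap_char != "-") cells[cells == gap_char] <- "-"
  if (is.null(symbols))
    symbols <- sort(unique(unlist(strsplit(
      cells[!cells %in% c("?", "-")], "/"))))
  character_matrix(names(parsed), cells, symbols = symbols)
}

#' Serialize a character matrix to NEXUS text
#'
#' @param x a [character_matrix()].
#' @param path optional file to write to.
#' @return the NEXUS document as a character vector of lines (invisibly when
#'   `path` is given).
#' @export
write_nexus <- function(x, path = NULL) {
  stopifnot(inherits(x, "character_matrix"))
  fmt_cell <- function(cell) {
    if (grepl("/", cell)) paste0("{", gsub("/", "", cell), "}") else cell
  }
  rows <- vapply(seq_len(x$n_taxa), function(i)
    paste0(x$taxon_names[i], "  ",
           paste(vapply(x$cells[i, ], fmt_cell, ""), collapse = "")), "")
  out <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", x$n_taxa, x$n_chars),
    sprintf('FORMAT MISSING=%s GAP=%s SYMBOLS="%s";',
            x$missing_char, x$gap_char, paste(x$symbols, collapse = "")),
    "MATRIX", rows, ";", "END;"
  )
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Read and write Newick trees
#'
#' Thin validating wrappers around [ape::read.tree()] / [ape::write.tree()].
#' Reading rejects duplicate leaf labels and reports malformed text;
#' single-leaf documents like `"A;"` are handled explicitly. Internal node
#' labels (e.g. bootstrap percentages) survive a round trip.
#'
#' @param text Newick text (for `read_newick`) or a path when `file` is used.
#' @param file optional path to read from / write to.
#' @param tree an [ape::phylo] tree (for `write_newick`).
#' @return `read_newick`: a `phylo` tree; `write_newick`: Newick text.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) stopf("supply text or file")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE),
                                   collapse = "")
  text <- trimws(text)
  # degenerate single-leaf document: ape mis-handles "A;"
  if (grepl("^[^();,]+;$", text)) {
    lab <- sub(";$", "", text)
    return(structure(
      list(edge = matrix(c(2L, 1L), 1, 2), Nnode = 1L, tip.label = lab),
      class = "phylo", order = "cladewise"))
  }
  tr <- tryCatch(ape::read.tree(text = text), error = function(e)
    stopf("malformed Newick: %s", conditionMessage(e)))
  if (is.null(tr)) stopf("malformed Newick (unbalanced parentheses?)")
  if (anyDuplicated(tr$tip.label))
    stopf("duplicate leaf label '%s' in Newick input",
          tr$tip.label[duplicated(tr$tip.label)][1])
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) == 1)
    out <- paste0(tree$tip.label, ";")
  else
    out <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Read a clast measurement table
#'
#' Expects CSV columns `id`, `axis1_mm`, `axis2_mm`, `axis3_mm` and optional
#' `mass_g`, `lithology`; axes may come in any order and are sorted into
#' a >= b >= c on construction.
#'
#' @param path CSV file path.
#' @return a list of [clast()] objects.
#' @export
read_clast_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "axis1_mm", "axis2_mm", "axis3_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing required column(s): %s",
                          paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    ax <- as.numeric(df[i, c("axis1_mm", "axis2_mm", "axis3_mm")])
    if (any(!is.finite(ax)) || any(ax <= 0))
      stopf("non-positive or missing axis in row %d (id '%s')",
            i, df$id[i])
    clast(ax[1], ax[2], ax[3],
          mass_g = if ("mass_g" %in% names(df))
            as.numeric(df$mass_g[i]) else NA_real_,
          lithology = if ("lithology" %in% names(df))
            as.character(df$lithology[i]) else NA_character_,
          id = as.character(df$id[i]))
  })
}

#' Write a clast table
#'
#' @param clasts list of [clast()] objects.
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
write_clast_table <- function(clasts, path) {
  df <- data.frame(
    id = vapply(clasts, function(x) as.character(x$id), ""),
    axis1_mm = vapply(clasts, `[[`, 0, "a"),
    axis2_mm = vapply(clasts, `[[`, 0, "b"),
    axis3_mm = vapply(clasts, `[[`, 0, "c"),
    mass_g = vapply(clasts, `[[`, 0, "mass_g"),
    lithology = vapply(clasts, function(x) as.character(x$lithology), ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an orientation-angle table
#'
#' Expects a CSV with an `angle_deg` column; angles are reduced modulo 360
#' into `[0, 360)`.
#'
#' @param path CSV file path.
#' @param axial treat angles as axial (undirected) data; default `TRUE`.
#' @return an [orientation_sample()].
#' @export
read_angle_table <- function(path, axial = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"angle_deg" %in% names(df))
    stopf("missing required column: angle_deg")
  orientation_sample(as.numeric(df$angle_deg), axial = axial)
}

#' Write an orientation-angle table
#'
#' @param sample an [orientation_sample()].
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
write_angle_table <- function(sample, path) {
  stopifnot(inherits(sample, "orientation_sample"))
  utils::write.csv(data.frame(angle_deg = sample$angles_deg), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
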