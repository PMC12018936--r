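# Readers and writers for the formats the pipeline touches: TNT xread and
# NEXUS character matrices, Newick trees, and delimited age / allometry tables.

## ---- character matrix container ------------------------------------------

#' Construct a discrete character matrix
#'
#' A `character_matrix` holds a taxa-by-characters block of discrete
#' morphological scores. Each cell is an ambiguity set of integer states:
#' a polymorphic/uncertain score such as `[01]` is the set \{0, 1\}, a missing
#' (`?`) or inapplicable (`-`) score is the empty set. Every character carries
#' an ordered flag: ordered (morphocline) characters are costed as Wagner
#' characters (cost |i - j|), unordered ones as Fitch characters (cost 1).
#'
#' @param cells a list-matrix (taxa in rows, characters in columns) whose
#'   elements are integer vectors of states; `integer(0)` marks missing.
#' @param taxa character vector of unique taxon labels; defaults to
#'   `rownames(cells)`.
#' @param ordered logical vector, one flag per character (default all
#'   unordered).
#' @return an object of class `character_matrix` with elements `taxa`,
#'   `n_chars`, `cells` and `ordered`.
#' @seealso [read_tnt_matrix()], [matrix_from_strings()]
#' @export
character_matrix <- function(cells, taxa = rownames(cells), ordered = NULL) {
  if (!is.matrix(cells) || !is.list(cells))
    .stopf("`cells` must be a list-matrix of integer state sets")
  if (is.null(taxa)) .stopf("taxon labels are required")
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) .stopf("duplicated taxon labels: %s",
    paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (length(taxa) != nrow(cells))
    .stopf("%d taxon labels for %d rows", length(taxa), nrow(cells))
  n_chars <- ncol(cells)
  ordered <- ordered %||% rep(FALSE, n_chars)
  if (length(ordered) != n_chars)
    .stopf("`ordered` must have one flag per character")
  cells[] <- lapply(cells, function(s) sort(unique(as.integer(s))))
  bad <- vapply(cells, function(s) anyNA(s) || any(s < 0), logical(1))
  if (any(bad)) .stopf("cells must contain non-negative integer states")
  rownames(cells) <- taxa
  structure(
    list(taxa = taxa, n_chars = n_chars, cells = cells,
         ordered = as.logical(ordered)),
    class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  miss <- mean(vapply(x$cells, length, integer(1)) == 0L)
  cat(sprintf("Character matrix: %d taxa x %d characters (%d ordered, %.0f%% missing)\n",
              length(x$taxa), x$n_chars, sum(x$ordered), 100 * miss))
  invisible(x)
}

#' Build a character matrix from per-taxon state strings
#'
#' Convenience constructor mainly used in examples and tests:
#' `matrix_from_strings(c(A = "010", B = "0[12]?"))`. The string syntax is the
#' TNT one: digits `0`-`9` and letters `A`-`V` (10-31) are states, `[..]`
#' (also `{..}`, `(..)`) is an ambiguity set, `?` and `-` are missing.
#'
#' @param strings named character vector, one state string per taxon.
#' @param ordered logical vector of per-character ordered flags.
#' @return a [character_matrix()].
#' @export
matrix_from_strings <- function(strings, ordered = NULL) {
  if (is.null(names(strings))) .stopf("`strings` must be named by taxon")
  rows <- lapply(strings, .parse_state_string)
  lens <- lengths(rows)
  if (length(unique(lens)) > 1L)
    .stopf("rows differ in character count: %s",
           paste(sprintf("%s=%d", names(strings), lens), collapse = ", "))
  cells <- matrix(do.call(c, rows), nrow = length(rows), byrow = TRUE)
  rownames(cells) <- names(strings)
  character_matrix(cells, ordered = ordered)
}

.SYMBOLS <- c(as.character(0:9), LETTERS[1:22])

.sym2int <- function(ch, where = "") {
  i <- match(toupper(ch), .SYMBOLS)
  if (anyNA(i)) .stopf("undeclared state symbol \"%s\"%s",
                       paste(ch[is.na(i)], collapse = ""), where)
  i - 1L
}

## parse one taxon's state string into a list of ambiguity sets
.parse_state_string <- function(s, taxon = NULL) {
  where <- if (is.null(taxon)) "" else sprintf(" in taxon %s", taxon)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- vector("list", length(chars))
  n_out <- 0L
  i <- 1L
  closers <- c("[" = "]", "{" = "}", "(" = ")")
  while (i <= length(chars)) {
    ch <- chars[i]
    n_out <- n_out + 1L
    if (ch %in% c("?", "-")) {
      out[[n_out]] <- integer(0)
      i <- i + 1L
    } else if (ch %in% names(closers)) {
      j <- i + 1L
      members <- character(0)
      while (j <= length(chars) && chars[j] != closers[[ch]]) {
        if (chars[j] != " ") members <- c(members, chars[j])
        j <- j + 1L
      }
      if (j > length(chars))
        .stopf("unclosed \"%s\" at position %d%s", ch, i, where)
      if (!length(members))
        .stopf("empty ambiguity set at position %d%s", i, where)
      out[[n_out]] <- .sym2int(members, where)
      i <- j + 1L
    } else {
      out[[n_out]] <- .sym2int(ch, where)
      i <- i + 1L
    }
  }
  out[seq_len(n_out)]
}

## ---- TNT xread ------------------------------------------------------------

#' Read a TNT xread character matrix
#'
#' Parses the `xread` block of a TNT file: declared character and taxon
#' counts, taxon rows (which may be line-wrapped or interleaved), bracketed
#' ambiguity sets, `?`/`-` missing scores, and `ccode`/`cc` ordering
#' directives (`+` marks additive = ordered characters, `-` non-additive;
#' indices are 0-based as in TNT). All other TNT commands are ignored with a
#' warning, as they do not affect scoring.
#'
#' @param path path to a TNT file.
#' @return a [character_matrix()].
#' @export
read_tnt_matrix <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  ## strip quoted titles before splitting on ';'
  txt <- gsub("'[^']*'", " ", txt)
  cmds <- strsplit(txt, ";", fixed = TRUE)[[1]]
  cmds <- trimws(cmds)
  cmds <- cmds[nzchar(cmds)]
  word <- tolower(sub("[[:space:]/].*$", "", cmds))
  ix <- which(word == "xread")
  if (!length(ix)) .stopf("no xread block found in %s", path)
  body <- sub("^\\s*\\S+", "", cmds[ix[1]])
  lines <- strsplit(body, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  head_toks <- strsplit(paste(lines, collapse = " "), "\\s+")[[1]]
  if (length(head_toks) < 2L ||
      anyNA(suppressWarnings(as.integer(head_toks[1:2]))))
    .stopf("xread block must declare \"nchar ntax\"")
  n_chars <- as.integer(head_toks[1])
  n_tax <- as.integer(head_toks[2])
  ## drop the two dimension tokens from the line stream
  lines[1] <- sub("^\\s*[0-9]+\\s*", "", lines[1])
  if (!nzchar(trimws(lines[1]))) lines <- lines[-1]
  lines[1] <- sub("^\\s*[0-9]+\\s*", "", lines[1])
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  ## number of cells the tokens encode, or NA when they are not state symbols
  cells_in <- function(toks) {
    tryCatch(sum(lengths(lapply(toks, function(tk)
      .parse_state_string(tk)))) + 0L,
      error = function(e) NA_integer_)
  }
  counts <- integer(0)       # parsed characters per taxon, by name
  rows <- list()
  current <- NULL
  for (ln in lines) {
    toks <- strsplit(ln, "\\s+")[[1]]
    ## a line continues the open row when the row is not yet full and the
    ## whole line reads as state symbols that fit in the remaining cells
    nc <- cells_in(toks)
    if (!is.null(current) && counts[[current]] < n_chars &&
        !is.na(nc) && counts[[current]] + nc <= n_chars) {
      chunks <- toks
    } else {
      current <- toks[1]
      chunks <- toks[-1]
      if (is.na(match(current, names(rows)))) {
        rows[[current]] <- list()
        counts[current] <- 0L
      }
    }
    for (tk in chunks) {
      if (counts[[current]] == n_chars) {
        ## row complete: a further token on the same line opens a new row
        current <- tk
        if (is.na(match(current, names(rows)))) {
          rows[[current]] <- list()
          counts[current] <- 0L
        }
        next
      }
      chunk <- .parse_state_string(tk, taxon = current)
      rows[[current]] <- c(rows[[current]], chunk)
      counts[current] <- counts[[current]] + length(chunk)
    }
    if (counts[[current]] > n_chars)
      .stopf("taxon %s has %d characters, %d declared",
             current, counts[[current]], n_chars)
  }
  short <- names(counts)[counts != n_chars]
  if (length(short))
    .stopf("taxon %s has %d characters, %d declared",
           short[1], counts[[short[1]]], n_chars)
  if (length(rows) != n_tax)
    .stopf("parsed %d taxa but %d declared", length(rows), n_tax)

  ordered <- rep(FALSE, n_chars)
  other <- character(0)
  for (k in seq_along(cmds)) {
    if (k == ix[1]) next
    if (word[k] %in% c("cc", "ccode")) {
      ordered <- .parse_ccode(cmds[k], n_chars, ordered)
    } else if (!word[k] %in% c("proc", "procedure", "xread")) {
      other <- c(other, word[k])
    }
  }
  if (length(other))
    .warnf("ignoring TNT command(s): %s", paste(unique(other), collapse = ", "))

  cells <- matrix(do.call(c, lapply(rows, identity)), nrow = length(rows),
                  byrow = TRUE)
  rownames(cells) <- names(rows)
  character_matrix(cells, ordered = ordered)
}

## parse a "ccode + 0 2 5.8 - 1" style directive; indices 0-based, "a.b" ranges
.parse_ccode <- function(cmd, n_chars, ordered) {
  toks <- strsplit(sub("^\\s*\\S+\\s*", "", cmd), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  mode <- NA
  for (tk in toks) {
    if (tk == "+") { mode <- TRUE; next }
    if (tk == "-") { mode <- FALSE; next }
    if (tk %in% c("[", "]", "*")) next
    if (grepl("^/", tk)) next              # weights: not used
    if (is.na(mode)) next
    if (tk == ".") { idx <- seq_len(n_chars) - 1L }
    else if (grepl("^[0-9]+\\.[0-9]+$", tk)) {
      ab <- as.integer(strsplit(tk, ".", fixed = TRUE)[[1]])
      idx <- seq(ab[1], ab[2])
    } else if (grepl("^[0-9]+$", tk)) {
      idx <- as.integer(tk)
    } else next
    idx <- idx[idx >= 0 & idx < n_chars]
    ordered[idx + 1L] <- mode
  }
  ordered
}

#' Write a character matrix as a TNT xread block
#'
#' @param x a [character_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tnt_matrix <- function(x, path) {
  stopifnot(inherits(x, "character_matrix"))
  fmt_cell <- function(s) {
    if (!length(s)) return("?")
    sym <- paste(.SYMBOLS[s + 1L], collapse = "")
    if (length(s) > 1L) paste0("[", sym, "]") else sym
  }
  lines <- c("xread", sprintf("%d %d", x$n_chars, length(x$taxa)))
  for (i in seq_along(x$taxa)) {
    row <- paste(vapply(x$cells[i, ], fmt_cell, character(1)), collapse = "")
    lines <- c(lines, paste(x$taxa[i], row))
  }
  lines <- c(lines, ";")
  if (any(x$ordered))
    lines <- c(lines, sprintf("ccode + %s;",
      paste(which(x$ordered) - 1L, collapse = " ")))
  lines <- c(lines, "proc/;")
  writeLines(lines, path)
  invisible(path)
}

## ---- NEXUS (read-only subset) --------------------------------------------

#' Read a NEXUS CHARACTERS/DATA matrix (subset)
#'
#' Reads the `MATRIX` block of a NEXUS file with the same cell syntax as
#' [read_tnt_matrix()] (here `{..}`/`(..)` ambiguity is usual). Ordering is
#' picked up from a `TYPESET` line containing `ord: <indices>` (1-based,
#' `a-b` ranges); all other assumptions are ignored.
#'
#' @param path path to a NEXUS file.
#' @return a [character_matrix()].
#' @export
read_nexus_matrix <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", " ", txt)    # NEXUS comments
  get1 <- function(re) {
    m <- regmatches(txt, regexpr(re, txt, ignore.case = TRUE))
    if (!length(m)) NA else m
  }
  nch <- get1("nchar\\s*=\\s*[0-9]+")
  ntx <- get1("ntax\\s*=\\s*[0-9]+")
  if (is.na(nch)) .stopf("no NCHAR declaration found")
  n_chars <- as.integer(sub(".*=\\s*", "", nch))
  mtx <- regmatches(txt, regexpr("matrix(.|\n)*?;", txt, ignore.case = TRUE))
  if (!length(mtx)) .stopf("no MATRIX block found in %s", path)
  body <- sub(";\\s*$", "", sub("^matrix", "", mtx, ignore.case = TRUE))
  ## protect ambiguity groups that may contain spaces, then tokenize
  body <- gsub("\\{\\s*([^}]*?)\\s*\\}", "{\\1}", body)
  toks <- strsplit(trimws(body), "\\s+")[[1]]
  toks <- gsub("^'(.*)'$", "\\1", toks)
  rows <- list(); counts <- integer(0)
  i <- 1L
  while (i <= length(toks)) {
    name <- toks[i]; i <- i + 1L
    if (is.na(match(name, names(rows)))) { rows[[name]] <- list(); counts[name] <- 0L }
    while (i <= length(toks) && counts[[name]] < n_chars) {
      chunk <- .parse_state_string(toks[i], taxon = name)
      rows[[name]] <- c(rows[[name]], chunk)
      counts[name] <- counts[[name]] + length(chunk)
      i <- i + 1L
    }
    if (counts[[name]] > n_chars)
      .stopf("taxon %s has %d characters, %d declared", name, counts[[name]], n_chars)
  }
  short <- names(counts)[counts != n_chars]
  if (length(short))
    .stopf("taxon %s has %d characters, %d declared", short[1], counts[[short[1]]], n_chars)
  if (!is.na(ntx) && length(rows) != as.integer(sub(".*=\\s*", "", ntx)))
    .stopf("parsed %d taxa but %d declared", length(rows),
           as.integer(sub(".*=\\s*", "", ntx)))
  ordered <- rep(FALSE, n_chars)
  ts <- regmatches(txt, regexpr("ord\\s*:[^,;]*", txt, ignore.case = TRUE))
  if (length(ts)) {
    for (tk in strsplit(sub("^[^:]*:", "", ts), "\\s+")[[1]]) {
      if (grepl("^[0-9]+-[0-9]+$", tk)) {
        ab <- as.integer(strsplit(tk, "-")[[1]]); idx <- seq(ab[1], ab[2])
      } else if (grepl("^[0-9]+$", tk)) idx <- as.integer(tk) else next
      ordered[idx[idx >= 1 & idx <= n_chars]] <- TRUE
    }
  }
  cells <- matrix(do.call(c, lapply(rows, identity)), nrow = length(rows),
                  byrow = TRUE)
  rownames(cells) <- names(rows)
  character_matrix(cells, ordered = ordered)
}

## ---- Newick ---------------------------------------------------------------

#' Read a Newick tree (or tree list)
#'
#' Thin wrapper around [ape::read.tree()] that turns silent failures into
#' errors and preserves polytomies and labels.
#'
#' @param path path to a Newick file; may contain several trees.
#' @return a `phylo` object, or a `multiPhylo` list if the file holds more
#'   than one tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) .stopf("failed to parse Newick in %s (unbalanced parentheses?)", path)
  tr
}

#' Write trees to a Newick file
#'
#' @param tree a `phylo` or `multiPhylo` object (or list of `phylo`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (is.list(tree) && !.is_phylo(tree)) class(tree) <- "multiPhylo"
  ape::write.tree(tree, file = path)
  invisible(path)
}

## ---- delimited tables -----------------------------------------------------

#' Read an age or allometry table
#'
#' Tables are comma- or tab-delimited (auto-detected from the header line).
#' The `age` schema requires columns `taxon`, `fad`, `lad` (Ma; first/last
#' appearance data, `fad >= lad >= 0`). The `allometry` schema requires
#' `taxon`, `specimen`, `hw_cm` and optionally `tl_cm` (head width and total
#' length in cm; `tl_cm` empty for fossil specimens).
#'
#' @param path path to the delimited file.
#' @param schema `"age"` or `"allometry"`.
#' @return a data frame of validated records.
#' @export
read_table <- function(path, schema = c("age", "allometry")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          colClasses = "character", comment.char = "")
  names(df) <- tolower(trimws(names(df)))
  need <- switch(schema, age = c("taxon", "fad", "lad"),
                 allometry = c("taxon", "specimen", "hw_cm"))
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("missing required column(s): %s", paste(miss, collapse = ", "))
  num <- function(col) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & nzchar(raw) & !toupper(raw) %in% c("NA", "?"))
    if (length(bad)) .stopf("non-numeric value \"%s\" in column %s, line %d",
                            raw[bad[1]], col, bad[1] + 1L)
    v
  }
  if (schema == "age") {
    out <- data.frame(taxon = df$taxon, fad = num("fad"), lad = num("lad"),
                      stringsAsFactors = FALSE)
    if (anyDuplicated(out$taxon))
      .stopf("duplicated taxon in age table: %s",
             out$taxon[duplicated(out$taxon)][1])
    if (anyNA(out$fad) || anyNA(out$lad)) .stopf("fad/lad must be complete")
    bad <- which(out$fad < out$lad | out$lad < 0)
    if (length(bad))
      .stopf("invalid ages for taxon %s (need fad >= lad >= 0), line %d",
             out$taxon[bad[1]], bad[1] + 1L)
  } else {
    out <- data.frame(taxon = df$taxon, specimen = df$specimen,
                      hw_cm = num("hw_cm"),
                      tl_cm = if ("tl_cm" %in% names(df)) num("tl_cm") else NA_real_,
                      stringsAsFactors = FALSE)
    bad <- which(is.na(out$hw_cm) | out$hw_cm <= 0)
    if (length(bad)) .stopf("non-positive or missing hw_cm, line %d", bad[1] + 1L)
    bad <- which(!is.na(out$tl_cm) & out$tl_cm <= 0)
    if (length(bad)) .stopf("non-positive tl_cm, line %d", bad[1] + 1L)
  }
  out
}
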