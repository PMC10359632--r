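## Minimal CIF 1.1 syntax layer: enough of the grammar for PDBx/mmCIF v5
## atom_site blocks and for the package's own parameter/library files.
## Handles data_ blocks, loop_ tables, '...'/"..." quoting, # comments and
## ;-delimited multi-line text fields. Dictionaries are not validated;
## unknown categories are carried as plain tables.

cif_tokenize <- function(lines) {
  tokens <- character()
  lineno <- integer()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[[i]]
    if (startsWith(ln, ";")) {
      # multi-line text field
      buf <- sub("^;", "", ln)
      start <- i
      i <- i + 1L
      while (i <= n && !startsWith(lines[[i]], ";")) {
        buf <- paste(buf, lines[[i]], sep = "\n")
        i <- i + 1L
      }
      if (i > n) stop("unterminated ';' text field starting at line ", start,
                      call. = FALSE)
      tokens <- c(tokens, buf)
      lineno <- c(lineno, start)
      i <- i + 1L
      next
    }
    m <- gregexpr("'[^']*'|\"[^\"]*\"|#.*$|\\S+", ln)[[1]]
    if (m[1] != -1) {
      parts <- regmatches(ln, list(m))[[1]]
      for (p in parts) {
        if (startsWith(p, "#")) break
        if ((startsWith(p, "'") && endsWith(p, "'") && nchar(p) >= 2) ||
            (startsWith(p, "\"") && endsWith(p, "\"") && nchar(p) >= 2)) {
          p <- substr(p, 2, nchar(p) - 1)
        }
        tokens <- c(tokens, p)
        lineno <- c(lineno, i)
      }
    }
    i <- i + 1L
  }
  list(tokens = tokens, lineno = lineno)
}

is_cif_tag <- function(x) startsWith(x, "_")

is_cif_reserved <- function(x) {
  grepl("^(data_|loop_$|stop_$|global_$|save_)", x, ignore.case = TRUE)
}

## Parse CIF text into a list of data blocks. Each block is
## list(name, items = named character list, loops = list of data.frames
## whose column names are the full tags).
cif_parse <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
  tk <- cif_tokenize(lines)
  tokens <- tk$tokens
  lineno <- tk$lineno
  blocks <- list()
  cur <- NULL
  i <- 1L
  n <- length(tokens)
  flush <- function(blocks, cur) {
    if (!is.null(cur)) blocks[[cur$name]] <- cur
    blocks
  }
  while (i <= n) {
    tok <- tokens[[i]]
    if (grepl("^data_", tok, ignore.case = TRUE)) {
      blocks <- flush(blocks, cur)
      cur <- list(name = sub("^data_", "", tok, ignore.case = TRUE),
                  items = list(), loops = list())
      i <- i + 1L
    } else if (tolower(tok) == "loop_") {
      if (is.null(cur)) cur <- list(name = "", items = list(), loops = list())
      i <- i + 1L
      tags <- character()
      while (i <= n && is_cif_tag(tokens[[i]])) {
        tags <- c(tags, tokens[[i]])
        i <- i + 1L
      }
      if (length(tags) == 0L) stop("loop_ without tags near line ",
                                   lineno[[min(i, n)]], call. = FALSE)
      vals <- character()
      while (i <= n && !is_cif_tag(tokens[[i]]) &&
             !is_cif_reserved(tokens[[i]])) {
        vals <- c(vals, tokens[[i]])
        i <- i + 1L
      }
      if (length(vals) %% length(tags) != 0L) {
        stop("loop with ", length(tags), " columns has ", length(vals),
             " values (not a multiple); near line ", lineno[[i - 1L]],
             call. = FALSE)
      }
      tbl <- as.data.frame(matrix(vals, ncol = length(tags), byrow = TRUE),
                           stringsAsFactors = FALSE)
      names(tbl) <- tags
      cur$loops[[length(cur$loops) + 1L]] <- tbl
    } else if (is_cif_tag(tok)) {
      if (is.null(cur)) cur <- list(name = "", items = list(), loops = list())
      if (i + 1L > n) stop("tag ", tok, " has no value", call. = FALSE)
      cur$items[[tok]] <- tokens[[i + 1L]]
      i <- i + 2L
    } else {
      stop("unexpected token '", substr(tok, 1, 40), "' at line ",
           lineno[[i]], call. = FALSE)
    }
  }
  blocks <- flush(blocks, cur)
  blocks
}

## Locate the loop of a block that contains tags of the given category
## (e.g. "_atom_site"). Returns NULL when absent.
cif_find_loop <- function(block, category) {
  prefix <- paste0(category, ".")
  for (lp in block$loops) {
    if (any(startsWith(names(lp), prefix))) return(lp)
  }
  # single-row categories may be written as plain items
  if (length(block$items) == 0) return(NULL)
  it <- block$items[startsWith(names(block$items), prefix)]
  if (length(it) > 0) {
    tbl <- as.data.frame(it, optional = TRUE, stringsAsFactors = FALSE)
    names(tbl) <- names(it)
    return(tbl)
  }
  NULL
}

## Convert loop columns to numeric with line-context errors.
cif_numeric <- function(x, tag) {
  y <- suppressWarnings(as.numeric(x))
  bad <- is.na(y) & !(x %in% c(".", "?"))
  if (any(bad)) {
    stop("malformed numeric value '", x[which(bad)[1]], "' in ", tag,
         " (row ", which(bad)[1], ")", call. = FALSE)
  }
  y[x %in% c(".", "?")] <- NA_real_
  y
}

cif_quote <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "."
  needs <- grepl("[ '\"#]", x) | x == "" | grepl("^_", x)
  x[needs] <- paste0("'", gsub("'", "", x[needs]), "'")
  x
}

## Serialize a data.frame as an aligned loop_ category.
cif_format_loop <- function(tbl) {
  cols <- vapply(tbl, function(col) format(cif_quote(col), width = 0),
                 FUN.VALUE = character(nrow(tbl)))
  if (nrow(tbl) == 1L) cols <- matrix(cols, nrow = 1L)
  widths <- apply(nchar(cols), 2, max)
  for (j in seq_len(ncol(cols))) {
    cols[, j] <- formatC(cols[, j], width = -widths[j], flag = "-")
  }
  body <- apply(cols, 1, paste, collapse = " ")
  c("loop_", names(tbl), trimws(body, which = "right"))
}
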