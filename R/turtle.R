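# Minimal Turtle / TriG reader and writer for the constrained RDF profile
# this package emits: prefixed names, plain and typed string literals,
# predicate-object lists (";"), object lists (","), and (for TriG) named
# graphs written as `graph { ... }`. Blank nodes, collections and
# multi-line literals are out of profile.

.ttl_prefixes <- c(
  carex = "http://example.org/carex#",
  chr   = "http://example.org/carex/character#",
  crm   = "http://example.org/carex/matrix#",
  obo   = "http://purl.obolibrary.org/obo/",
  oai   = "http://example.org/oai#",
  rdf   = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs  = "http://www.w3.org/2000/01/rdf-schema#",
  owl   = "http://www.w3.org/2002/07/owl#",
  xsd   = "http://www.w3.org/2001/XMLSchema#"
)

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

ttl_unescape <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    res <- character(0)
    j <- 1L
    n <- nchar(s)
    while (j <= n) {
      ch <- substr(s, j, j)
      if (ch == "\\" && j < n) {
        nxt <- substr(s, j + 1L, j + 1L)
        res <- c(res, switch(nxt,
          "n" = "\n", "r" = "\r", "t" = "\t",
          "\"" = "\"", "\\" = "\\", nxt
        ))
        j <- j + 2L
      } else {
        res <- c(res, ch)
        j <- j + 1L
      }
    }
    out[[i]] <- paste0(res, collapse = "")
  }
  out
}

# Tokenize a Turtle/TriG document. Comments (# to end of line, outside
# string literals) are stripped. Returns a character vector of tokens;
# literal tokens keep their surrounding quotes (plus any ^^datatype).
ttl_tokenize <- function(text, path = "<text>") {
  src <- paste(text, collapse = "\n")
  n <- nchar(src)
  tokens <- character(0)
  i <- 1L
  line <- 1L
  tok_lines <- integer(0)
  while (i <= n) {
    ch <- substr(src, i, i)
    if (ch == "\n") {
      line <- line + 1L
      i <- i + 1L
    } else if (grepl("^[ \t\r]$", ch)) {
      i <- i + 1L
    } else if (ch == "#") {
      while (i <= n && substr(src, i, i) != "\n") i <- i + 1L
    } else if (ch == "\"") {
      j <- i + 1L
      while (j <= n) {
        cj <- substr(src, j, j)
        if (cj == "\\") {
          j <- j + 2L
        } else if (cj == "\"") {
          break
        } else {
          if (cj == "\n") line <- line + 1L
          j <- j + 1L
        }
      }
      if (j > n) {
        stop_charrec(sprintf("%s: unterminated string literal at line %d", path, line),
                     class = "format")
      }
      end <- j
      # optional ^^datatype or @lang
      rest <- substr(src, end + 1L, min(n, end + 64L))
      suffix <- regmatches(rest, regexpr("^(\\^\\^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]+|@[A-Za-z-]+)", rest))
      extra <- if (length(suffix)) nchar(suffix) else 0L
      tokens <- c(tokens, substr(src, i, end + extra))
      tok_lines <- c(tok_lines, line)
      i <- end + extra + 1L
    } else if (ch == "<") {
      j <- regexpr(">", substr(src, i, n), fixed = TRUE)
      if (j < 0) stop_charrec(sprintf("%s: unterminated IRI at line %d", path, line), class = "format")
      tokens <- c(tokens, substr(src, i, i + j - 1L))
      tok_lines <- c(tok_lines, line)
      i <- i + j
    } else if (ch %in% c(".", ";", ",", "{", "}", "[", "]")) {
      tokens <- c(tokens, ch)
      tok_lines <- c(tok_lines, line)
      i <- i + 1L
    } else {
      m <- regexpr("^(@?[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_#/.-]*|@?[A-Za-z][A-Za-z0-9_-]*|[+-]?[0-9]+(\\.[0-9]+)?)",
                   substr(src, i, min(n, i + 512L)))
      if (m < 0) {
        stop_charrec(sprintf("%s: unexpected character '%s' at line %d", path, ch, line),
                     class = "format")
      }
      len <- attr(m, "match.length")
      tok <- substr(src, i, i + len - 1L)
      # a prefixed name must not swallow the statement-terminating dot
      while (grepl("\\.$", tok)) {
        tok <- substr(tok, 1L, nchar(tok) - 1L)
        len <- len - 1L
      }
      tokens <- c(tokens, tok)
      tok_lines <- c(tok_lines, line)
      i <- i + len
    }
  }
  attr(tokens, "lines") <- tok_lines
  tokens
}

is_literal_token <- function(tok) startsWith(tok, "\"")

parse_literal_token <- function(tok) {
  m <- regmatches(tok, regexpr("\"(\\\\.|[^\"\\\\])*\"", tok))
  value <- ttl_unescape(substr(m, 2L, nchar(m) - 1L))
  dtype <- sub("^\"(\\\\.|[^\"\\\\])*\"", "", tok)
  dtype <- sub("^\\^\\^", "", dtype)
  list(value = value, datatype = if (nzchar(dtype)) dtype else NA_character_)
}

# Parse Turtle or TriG into a data.frame of triples with columns
# graph (NA for the default graph), s, p, o, lit (logical), dtype.
parse_rdf <- function(path_or_text, path = NULL) {
  if (!is.null(path)) {
    text <- readLines(path, warn = FALSE, encoding = "UTF-8")
    label <- path
  } else if (length(path_or_text) == 1L && file.exists(path_or_text)) {
    text <- readLines(path_or_text, warn = FALSE, encoding = "UTF-8")
    label <- path_or_text
  } else {
    text <- path_or_text
    label <- "<text>"
  }
  toks <- ttl_tokenize(text, path = label)
  lines <- attr(toks, "lines")
  prefixes <- character(0)
  rows <- list()
  i <- 1L
  n <- length(toks)
  err <- function(msg, at = i) {
    ln <- if (at <= length(lines)) lines[[at]] else lines[[length(lines)]]
    stop_charrec(sprintf("%s: %s near line %d", label, msg, ln), class = "format")
  }

  parse_triples <- function(graph, stop_at_brace) {
    while (i <= n) {
      if (stop_at_brace && toks[[i]] == "}") {
        i <<- i + 1L
        return(invisible(NULL))
      }
      subj <- toks[[i]]; i <<- i + 1L
      repeat {
        if (i > n) err("unexpected end of input (predicate expected)")
        pred <- toks[[i]]; i <<- i + 1L
        if (pred == "a") pred <- "rdf:type"
        repeat {
          if (i > n) err("unexpected end of input (object expected)")
          obj <- toks[[i]]; i <<- i + 1L
          if (is_literal_token(obj)) {
            lit <- parse_literal_token(obj)
            rows[[length(rows) + 1L]] <<- list(graph = graph, s = subj, p = pred,
                                               o = lit$value, lit = TRUE,
                                               dtype = lit$datatype)
          } else {
            rows[[length(rows) + 1L]] <<- list(graph = graph, s = subj, p = pred,
                                               o = obj, lit = FALSE,
                                               dtype = NA_character_)
          }
          if (i <= n && toks[[i]] == ",") { i <<- i + 1L; next }
          break
        }
        if (i <= n && toks[[i]] == ";") {
          i <<- i + 1L
          # tolerate trailing ";" before "."
          if (i <= n && toks[[i]] %in% c(".", "}")) next
          next
        }
        break
      }
      if (i > n || toks[[i]] != ".") err("expected '.' at end of statement")
      i <<- i + 1L
    }
    if (stop_at_brace) err("unexpected end of input (missing '}')")
    invisible(NULL)
  }

  while (i <= n) {
    tok <- toks[[i]]
    if (tok %in% c("@prefix", "PREFIX")) {
      if (i + 2L > n) err("incomplete @prefix directive")
      pfx <- sub(":$", "", toks[[i + 1L]])
      iri <- toks[[i + 2L]]
      prefixes[[pfx]] <- substr(iri, 2L, nchar(iri) - 1L)
      i <- i + 3L
      if (i <= n && toks[[i]] == ".") i <- i + 1L
    } else if (i + 1L <= n && toks[[i + 1L]] == "{") {
      graph <- tok
      i <- i + 2L
      parse_triples(graph, stop_at_brace = TRUE)
    } else {
      # default-graph statement: parse one statement
      subj <- toks[[i]]; i <- i + 1L
      repeat {
        if (i > n) err("unexpected end of input (predicate expected)")
        pred <- toks[[i]]; i <- i + 1L
        if (pred == "a") pred <- "rdf:type"
        repeat {
          if (i > n) err("unexpected end of input (object expected)")
          obj <- toks[[i]]; i <- i + 1L
          if (is_literal_token(obj)) {
            lit <- parse_literal_token(obj)
            rows[[length(rows) + 1L]] <- list(graph = NA_character_, s = subj, p = pred,
                                              o = lit$value, lit = TRUE,
                                              dtype = lit$datatype)
          } else {
            rows[[length(rows) + 1L]] <- list(graph = NA_character_, s = subj, p = pred,
                                              o = obj, lit = FALSE,
                                              dtype = NA_character_)
          }
          if (i <= n && toks[[i]] == ",") { i <- i + 1L; next }
          break
        }
        if (i <= n && toks[[i]] == ";") {
          i <- i + 1L
          if (i <= n && toks[[i]] == ".") next
          next
        }
        break
      }
      if (i > n || toks[[i]] != ".") err("expected '.' at end of statement")
      i <- i + 1L
    }
  }

  df <- if (length(rows)) {
    do.call(rbind, lapply(rows, function(r) {
      data.frame(graph = r$graph, s = r$s, p = r$p, o = r$o, lit = r$lit,
                 dtype = r$dtype, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(graph = character(0), s = character(0), p = character(0),
               o = character(0), lit = logical(0), dtype = character(0),
               stringsAsFactors = FALSE)
  }
  attr(df, "prefixes") <- prefixes
  df
}

format_object <- function(o, lit, dtype) {
  if (!lit) return(o)
  out <- paste0("\"", ttl_escape(o), "\"")
  if (!is.na(dtype)) out <- paste0(out, "^^", dtype)
  out
}

prefix_block <- function(prefixes = .ttl_prefixes) {
  paste0("@prefix ", names(prefixes), ": <", unname(prefixes), "> .")
}

# Serialize triples (data.frame as produced by parse_rdf) grouped by
# subject, preserving row order within each subject group.
serialize_subject_block <- function(df, indent = "") {
  stopifnot(nrow(df) > 0L)
  subj <- df$s[[1L]]
  lines <- character(0)
  preds <- unique(df$p)
  parts <- vapply(preds, function(p) {
    sel <- df[df$p == p, , drop = FALSE]
    objs <- mapply(format_object, sel$o, sel$lit, sel$dtype, USE.NAMES = FALSE)
    pd <- if (p == "rdf:type") "a" else p
    paste0(pd, " ", paste(objs, collapse = ", "))
  }, character(1))
  body <- paste0(indent, "    ", parts)
  lines <- c(paste0(indent, subj, " ", sub("^\\s+", "", body[[1L]])),
             if (length(body) > 1L) body[-1L])
  # join with " ;" line endings, final " ."
  nlines <- length(lines)
  if (nlines > 1L) {
    lines[seq_len(nlines - 1L)] <- paste0(lines[seq_len(nlines - 1L)], " ;")
  }
  lines[[nlines]] <- paste0(lines[[nlines]], " .")
  lines
}

write_turtle <- function(triples, path, prefixes = .ttl_prefixes) {
  lines <- prefix_block(prefixes)
  subjects <- unique(triples$s)
  for (s in subjects) {
    lines <- c(lines, "", serialize_subject_block(triples[triples$s == s, , drop = FALSE]))
  }
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop_charrec(
                    sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
                    class = "io"))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

write_trig <- function(triples, path, prefixes = .ttl_prefixes) {
  lines <- prefix_block(prefixes)
  default <- triples[is.na(triples$graph), , drop = FALSE]
  for (s in unique(default$s)) {
    lines <- c(lines, "", serialize_subject_block(default[default$s == s, , drop = FALSE]))
  }
  for (g in unique(triples$graph[!is.na(triples$graph)])) {
    sel <- triples[!is.na(triples$graph) & triples$graph == g, , drop = FALSE]
    lines <- c(lines, "", paste0(g, " {"))
    for (s in unique(sel$s)) {
      lines <- c(lines, serialize_subject_block(sel[sel$s == s, , drop = FALSE], indent = "    "))
    }
    lines <- c(lines, "}")
  }
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop_charrec(
                    sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
                    class = "io"))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Canonical string form of a triple set, for set-equality comparisons
# (blank nodes are out of profile, so renaming is not an issue).
triple_set <- function(df) {
  sort(paste(ifelse(is.na(df$graph), "", df$graph), df$s, df$p,
             mapply(format_object, df$o, df$lit, df$dtype, USE.NAMES = FALSE)))
}
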