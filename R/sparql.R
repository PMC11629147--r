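# Embedded SPARQL SELECT engine.
#
# Supports the fragment the query compiler emits, plus plain SELECTs:
#   PREFIX declarations; SELECT [DISTINCT] ?v... | * |
#   (COUNT(DISTINCT ?v) AS ?n); WHERE { basic graph patterns with `a`,
#   IRIs, prefixed names, typed/plain literals; FILTER with comparisons,
#   && / || / !, CONTAINS(), STR() }; ORDER BY [ASC|DESC]; LIMIT.
# Evaluation: naive BGP join ordering (most-constrained pattern first),
# default graph = union of all named graphs.

# --- terms -----------------------------------------------------------------

# canonical binding encoding, injective across kinds so joins are plain
# string equality: IRIs "<...>", literals "\"lex\"^^ot"
enc_term <- function(o, ot) ifelse(ot == "iri", paste0("<", o, ">"),
                                   paste0('"', o, '"^^', ot))
dec_value <- function(x) {
  iri <- startsWith(x, "<")
  out <- x
  out[iri] <- substr(x[iri], 2L, nchar(x[iri]) - 1L)
  lit <- !iri
  out[lit] <- sub('\\^\\^[a-z]+$', "", substr(x[lit], 2L, nchar(x[lit])))
  out[lit] <- substr(out[lit], 1L, nchar(out[lit]) - 1L)
  out
}
dec_kind <- function(x) ifelse(startsWith(x, "<"), "iri", sub('^.*\\^\\^', "", x))

# --- tokenizer -------------------------------------------------------------

sparql_tokenize <- function(q) {
  pats <- c(
    ws      = "^[\\s]+",
    comment = "^#[^\\n]*",
    iri     = "^<[^<>\\s]*>",
    var     = "^\\?[A-Za-z_][A-Za-z0-9_]*",
    string  = '^"(?:[^"\\\\]|\\\\.)*"',
    dtype   = "^\\^\\^",
    number  = "^[+-]?[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?",
    pname   = "^[A-Za-z_][A-Za-z0-9_-]*:[A-Za-z0-9_.%-]*",
    name    = "^[A-Za-z_][A-Za-z0-9_]*",
    op      = "^(?:&&|\\|\\||!=|<=|>=|=|<|>|!|\\(|\\)|\\{|\\}|\\.|;|,|\\*)"
  )
  toks <- list(); pos <- 1L; n <- nchar(q)
  while (pos <= n) {
    rest <- substr(q, pos, n)
    hit <- FALSE
    for (ty in names(pats)) {
      m <- regexpr(pats[[ty]], rest, perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        if (!ty %in% c("ws", "comment"))
          toks[[length(toks) + 1L]] <- list(type = ty,
                                            text = substr(rest, 1L, len))
        pos <- pos + len; hit <- TRUE; break
      }
    }
    if (!hit) stop("SPARQL parse error near: ",
                   substr(q, pos, min(n, pos + 30L)))
  }
  toks
}

# --- parser ----------------------------------------------------------------

sparql_parse <- function(q) {
  toks <- sparql_tokenize(q)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else list(type = "eof", text = "")
  advance <- function() { t <- peek(); i <<- i + 1L; t }
  expect <- function(text) {
    t <- advance()
    if (!identical(toupper(t$text), toupper(text)))
      stop("SPARQL parse error: expected '", text, "', got '", t$text, "'")
    t
  }
  is_kw <- function(t, kw) t$type == "name" && toupper(t$text) == kw

  prefixes <- list()
  while (is_kw(peek(), "PREFIX")) {
    advance()
    pn <- advance()
    if (pn$type != "pname") stop("SPARQL parse error: bad PREFIX name")
    iri <- advance()
    if (iri$type != "iri") stop("SPARQL parse error: PREFIX needs an IRI")
    prefixes[[sub(":.*$", "", pn$text)]] <- substr(iri$text, 2L, nchar(iri$text) - 1L)
  }

  resolve <- function(t) {
    # token -> term list(type, value, ot)
    if (t$type == "iri")
      return(list(type = "iri", value = substr(t$text, 2L, nchar(t$text) - 1L)))
    if (t$type == "pname") {
      pfx <- sub(":.*$", "", t$text)
      loc <- sub("^[^:]*:", "", t$text)
      base <- prefixes[[pfx]]
      if (is.null(base)) stop("SPARQL: undeclared prefix '", pfx, ":'")
      return(list(type = "iri", value = paste0(base, loc)))
    }
    if (t$type == "var") return(list(type = "var", value = substr(t$text, 2L, nchar(t$text))))
    if (t$type == "name" && t$text == "a") return(list(type = "iri", value = RDF_TYPE))
    if (t$type == "number") {
      ot <- if (grepl("[.eE]", t$text)) "decimal" else "integer"
      return(list(type = "lit", value = t$text, ot = ot))
    }
    if (t$type == "string") {
      lex <- gsub('\\\\(.)', "\\1", substr(t$text, 2L, nchar(t$text) - 1L))
      ot <- "string"
      if (peek()$type == "dtype") {
        advance(); dt <- advance()
        dti <- resolve(dt)$value
        ot <- switch(sub(".*#", "", dti), integer = "integer",
                     decimal = "decimal", double = "decimal", "string")
      }
      return(list(type = "lit", value = lex, ot = ot))
    }
    stop("SPARQL parse error: unexpected token '", t$text, "'")
  }

  expect("SELECT")
  distinct <- FALSE
  if (is_kw(peek(), "DISTINCT")) { advance(); distinct <- TRUE }
  proj <- character(); agg <- NULL; star <- FALSE
  repeat {
    t <- peek()
    if (t$type == "var") { advance(); proj <- c(proj, substr(t$text, 2L, nchar(t$text))) }
    else if (t$text == "*") { advance(); star <- TRUE }
    else if (t$text == "(") {
      advance()
      fun <- advance()
      if (!is_kw(fun, "COUNT")) stop("SPARQL: only COUNT aggregate supported")
      expect("(")
      cdist <- FALSE
      if (is_kw(peek(), "DISTINCT")) { advance(); cdist <- TRUE }
      v <- advance()
      if (v$type != "var") stop("SPARQL: COUNT expects a variable")
      expect(")"); expect("AS")
      as_v <- advance()
      if (as_v$type != "var") stop("SPARQL: AS expects a variable")
      expect(")")
      agg <- list(var = substr(v$text, 2L, nchar(v$text)), distinct = cdist,
                  as = substr(as_v$text, 2L, nchar(as_v$text)))
    } else break
  }
  expect("WHERE"); expect("{")

  patterns <- list(); filters <- list()

  parse_expr <- function() {
    parse_or <- function() {
      left <- parse_and()
      while (peek()$text == "||") { advance(); left <- list(op = "||", l = left, r = parse_and()) }
      left
    }
    parse_and <- function() {
      left <- parse_rel()
      while (peek()$text == "&&") { advance(); left <- list(op = "&&", l = left, r = parse_rel()) }
      left
    }
    parse_rel <- function() {
      if (peek()$text == "!") { advance(); return(list(op = "!", l = parse_rel())) }
      if (peek()$text == "(") { advance(); e <- parse_or(); expect(")"); return(e) }
      if (is_kw(peek(), "CONTAINS")) {
        advance(); expect("(")
        a <- parse_prim(); expect(","); b <- parse_prim(); expect(")")
        return(list(op = "contains", l = a, r = b))
      }
      left <- parse_prim()
      t <- peek()
      if (t$text %in% c("=", "!=", "<", "<=", ">", ">=")) {
        advance()
        return(list(op = t$text, l = left, r = parse_prim()))
      }
      left
    }
    parse_prim <- function() {
      if (is_kw(peek(), "STR")) {
        advance(); expect("(")
        inner <- parse_prim(); expect(")")
        return(list(op = "str", l = inner))
      }
      list(op = "term", term = resolve(advance()))
    }
    parse_or()
  }

  repeat {
    t <- peek()
    if (t$text == "}") { advance(); break }
    if (is_kw(t, "FILTER")) {
      advance(); expect("(")
      filters[[length(filters) + 1L]] <- parse_expr()
      expect(")")
      if (peek()$text == ".") advance()
      next
    }
    subj <- resolve(advance())
    repeat {
      pred <- resolve(advance())
      repeat {
        obj <- resolve(advance())
        patterns[[length(patterns) + 1L]] <- list(s = subj, p = pred, o = obj)
        if (peek()$text == ",") { advance(); next }
        break
      }
      if (peek()$text == ";") {
        advance()
        if (peek()$text %in% c(".", "}")) break
        next
      }
      break
    }
    if (peek()$text == ".") advance()
  }

  order_by <- NULL; order_desc <- FALSE; limit <- NULL
  while (peek()$type != "eof") {
    t <- advance()
    if (is_kw(t, "ORDER")) {
      expect("BY")
      if (is_kw(peek(), "ASC") || is_kw(peek(), "DESC")) {
        order_desc <- is_kw(peek(), "DESC"); advance(); expect("(")
        v <- advance(); expect(")")
      } else v <- advance()
      if (v$type != "var") stop("SPARQL: ORDER BY expects a variable")
      order_by <- substr(v$text, 2L, nchar(v$text))
    } else if (is_kw(t, "LIMIT")) {
      limit <- as.integer(advance()$text)
    } else stop("SPARQL parse error: unexpected '", t$text, "'")
  }

  list(distinct = distinct, proj = proj, star = star, agg = agg,
       patterns = patterns, filters = filters,
       order_by = order_by, order_desc = order_desc, limit = limit)
}

# --- evaluator -------------------------------------------------------------

pattern_vars <- function(p)
  unlist(lapply(p[c("s", "p", "o")], function(t) if (t$type == "var") t$value))

match_pattern <- function(T, pat) {
  idx <- rep(TRUE, nrow(T))
  if (pat$s$type == "iri") idx <- idx & T$s == pat$s$value
  if (pat$p$type == "iri") idx <- idx & T$p == pat$p$value
  if (pat$o$type == "iri") idx <- idx & T$ot == "iri" & T$o == pat$o$value
  if (pat$o$type == "lit") {
    if (pat$o$ot %in% c("integer", "decimal"))
      idx <- idx & T$ot %in% c("integer", "decimal") &
        !is.na(suppressWarnings(as.numeric(T$o))) &
        suppressWarnings(as.numeric(T$o)) == as.numeric(pat$o$value)
    else idx <- idx & T$ot == "string" & T$o == pat$o$value
  }
  m <- T[idx, , drop = FALSE]
  # paste0() maps zero-length inputs to "", so guard the no-match case
  enc_iri0 <- function(x) if (length(x)) paste0("<", x, ">") else character(0)
  out <- list()
  if (pat$s$type == "var") out[[pat$s$value]] <- enc_iri0(m$s)
  if (pat$p$type == "var") out[[pat$p$value]] <- enc_iri0(m$p)
  if (pat$o$type == "var") {
    ov <- if (nrow(m)) enc_term(m$o, m$ot) else character(0)
    if (pat$o$value %in% names(out)) {
      keep <- out[[pat$o$value]] == ov
      out <- lapply(out, `[`, keep); ov <- ov[keep]
    }
    out[[pat$o$value]] <- ov
  }
  if (pat$s$type == "var" && pat$p$type == "var" && pat$s$value == pat$p$value) {
    keep <- out[[pat$s$value]] == paste0("<", m$p, ">")
    out <- lapply(out, `[`, keep)
  }
  if (!length(out)) {
    # fully ground pattern: acts as an existence check
    return(as.data.frame(matrix(nrow = if (nrow(m) > 0L) 1L else 0L, ncol = 0L)))
  }
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}

eval_filter_expr <- function(expr, B) {
  # returns per-row logical, or a list(value=..., numeric=...) column
  term_col <- function(t) {
    if (t$type == "var") {
      if (!t$value %in% names(B)) stop("FILTER references unbound ?", t$value)
      enc <- B[[t$value]]
      list(lex = dec_value(enc), kind = dec_kind(enc))
    } else if (t$type == "lit") {
      list(lex = rep(t$value, nrow(B)), kind = rep(t$ot, nrow(B)))
    } else {
      list(lex = rep(t$value, nrow(B)), kind = rep("iri", nrow(B)))
    }
  }
  ev <- function(e) {
    if (e$op %in% c("&&", "||")) {
      l <- ev(e$l); r <- ev(e$r)
      return(if (e$op == "&&") l & r else l | r)
    }
    if (e$op == "!") return(!ev(e$l))
    if (e$op == "contains") {
      a <- ev_col(e$l); b <- ev_col(e$r)
      return(mapply(grepl, b$lex, a$lex, MoreArgs = list(fixed = TRUE)))
    }
    if (e$op %in% c("=", "!=", "<", "<=", ">", ">=")) {
      a <- ev_col(e$l); b <- ev_col(e$r)
      num <- a$kind %in% c("integer", "decimal") & b$kind %in% c("integer", "decimal")
      av <- a$lex; bv <- b$lex
      res <- logical(length(av))
      if (any(num)) {
        an <- as.numeric(av[num]); bn <- as.numeric(bv[num])
        res[num] <- switch(e$op, "=" = an == bn, "!=" = an != bn,
                           "<" = an < bn, "<=" = an <= bn,
                           ">" = an > bn, ">=" = an >= bn)
      }
      if (any(!num)) {
        as_ <- av[!num]; bs <- bv[!num]
        res[!num] <- switch(e$op, "=" = as_ == bs, "!=" = as_ != bs,
                            "<" = as_ < bs, "<=" = as_ <= bs,
                            ">" = as_ > bs, ">=" = as_ >= bs)
      }
      return(res)
    }
    stop("FILTER: cannot evaluate operator '", e$op, "' as boolean")
  }
  ev_col <- function(e) {
    if (e$op == "term") return(term_col(e$term))
    if (e$op == "str") { c <- ev_col(e$l); return(list(lex = c$lex, kind = rep("string", length(c$lex)))) }
    stop("FILTER: unexpected operand")
  }
  ev(expr)
}

expr_vars <- function(e) {
  if (e$op == "term") return(if (e$term$type == "var") e$term$value else character())
  vars <- character()
  for (f in c("l", "r")) if (!is.null(e[[f]])) vars <- c(vars, expr_vars(e[[f]]))
  vars
}

eval_sparql <- function(T, q) {
  # T: triple data.frame (s, p, o, ot); q: parsed query
  bound <- function(pat) {
    n <- 0L
    for (f in c("s", "p", "o")) n <- n + (pat[[f]]$type != "var")
    n
  }
  todo <- q$patterns
  B <- NULL
  filters_left <- q$filters
  apply_ready_filters <- function(B) {
    if (is.null(B) || nrow(B) == 0L) return(B)
    keep <- vapply(filters_left, function(f) all(expr_vars(f) %in% names(B)), logical(1))
    for (f in filters_left[keep]) {
      if (nrow(B)) B <- B[eval_filter_expr(f, B), , drop = FALSE]
    }
    filters_left <<- filters_left[!keep]
    B
  }
  while (length(todo)) {
    if (is.null(B)) {
      pick <- which.max(vapply(todo, bound, integer(1)))
    } else {
      shares <- vapply(todo, function(p) length(intersect(pattern_vars(p), names(B))), integer(1))
      score <- shares * 10L + vapply(todo, bound, integer(1))
      pick <- which.max(score)
    }
    pat <- todo[[pick]]; todo <- todo[-pick]
    cand <- match_pattern(T, pat)
    if (is.null(B)) B <- cand
    else {
      by <- intersect(names(B), names(cand))
      B <- if (length(by)) merge(B, cand, by = by, stringsAsFactors = FALSE)
           else merge(B, cand, by = NULL)
    }
    if (nrow(B) == 0L) { todo <- list(); break }
    B <- apply_ready_filters(B)
  }
  if (is.null(B)) B <- data.frame()
  # any remaining filters (e.g. constant expressions)
  for (f in filters_left) if (nrow(B)) B <- B[eval_filter_expr(f, B), , drop = FALSE]

  if (!is.null(q$agg)) {
    v <- q$agg$var
    vals <- if (v %in% names(B)) B[[v]] else character()
    n <- if (q$agg$distinct) length(unique(vals)) else length(vals)
    out <- data.frame(x = as.character(n), stringsAsFactors = FALSE)
    names(out) <- q$agg$as
    attr(out, "kinds") <- stats::setNames("integer", q$agg$as)
    return(out)
  }

  proj <- if (q$star) names(B) else q$proj
  missing <- setdiff(proj, names(B))
  for (m in missing) B[[m]] <- rep(NA_character_, nrow(B))
  out <- B[, proj, drop = FALSE]
  if (q$distinct && nrow(out)) out <- out[!duplicated(out), , drop = FALSE]
  if (!is.null(q$order_by) && q$order_by %in% names(out) && nrow(out)) {
    o <- order(out[[q$order_by]], decreasing = q$order_desc)
    out <- out[o, , drop = FALSE]
  }
  if (!is.null(q$limit)) out <- utils::head(out, q$limit)
  kinds <- vapply(out, function(col) if (length(col)) dec_kind(col[1]) else "string",
                  character(1))
  for (j in seq_along(out)) out[[j]] <- dec_value(out[[j]])
  rownames(out) <- NULL
  attr(out, "kinds") <- kinds
  out
}
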