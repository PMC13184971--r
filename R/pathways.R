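#' Pathway definitions and the step-expression grammar
#'
#' A pathway database maps pathway elements (the unit at which genome-inferred
#' functional traits are scored) to a metabolic function and a broader domain,
#' and holds the ordered step expressions whose completion defines the trait.
#'
#' Step expressions form a small boolean-ish algebra over gene identifiers
#' (KEGG-ortholog or EC style strings):
#' \itemize{
#'   \item \code{IDENT} — a single required identifier;
#'   \item \code{ALL_OF} — all children are required (scored as the mean, so a
#'     step needing two identifiers with one present is half-complete);
#'   \item \code{ANY_OF} — alternative routes (scored as the maximum).
#' }
#'
#' The text grammar, as stored in pathway files: steps are separated by
#' \code{";"}; inside a step, whitespace means ALL_OF, \code{","} means
#' ANY_OF (comma binds less tightly than whitespace) and parentheses group.
#' For example \code{"K00001 (K00002,EC:1.1.1.1); K00003"} is a two-step
#' pathway whose first step requires K00001 together with either K00002 or
#' EC:1.1.1.1.
#'
#' @name pathway-grammar
NULL

expr_ident <- function(id) list(kind = "IDENT", id = id)
expr_all <- function(children) {
  if (length(children) == 1L) children[[1L]] else list(kind = "ALL_OF", children = children)
}
expr_any <- function(children) {
  if (length(children) == 1L) children[[1L]] else list(kind = "ANY_OF", children = children)
}

validate_expression <- function(expr) {
  if (!is.list(expr) || is.null(expr$kind)) stopf("malformed step expression")
  switch(expr$kind,
    IDENT = {
      if (!is.character(expr$id) || length(expr$id) != 1L || !nzchar(expr$id)) {
        stopf("IDENT node must carry one nonempty identifier")
      }
    },
    ALL_OF = ,
    ANY_OF = {
      if (length(expr$children) < 1L) stopf("%s node with empty child list", expr$kind)
      lapply(expr$children, validate_expression)
    },
    stopf("unknown expression kind '%s'", expr$kind)
  )
  invisible(TRUE)
}

tokenize_step <- function(text) {
  # identifiers are maximal runs of characters outside the grammar's
  # punctuation; "(", ")" and "," are single-character tokens
  pat <- "\\(|\\)|,|[^\\s(),;]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) character(0) else regmatches(text, list(m))[[1L]]
}

#' Parse one pathway step expression
#'
#' @param text a step in the grammar described in [pathway-grammar].
#' @return an expression tree (nested lists with a `kind` field).
#' @export
#' @examples
#' parse_step_expression("K00001 (K00002,EC:1.1.1.1)")
parse_step_expression <- function(text) {
  toks <- tokenize_step(text)
  if (length(toks) == 0L) stopf("empty step expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }

  parse_alt <- function() {
    parts <- list(parse_seq())
    while (!is.na(peek()) && peek() == ",") {
      advance()
      parts[[length(parts) + 1L]] <- parse_seq()
    }
    expr_any(parts)
  }
  parse_seq <- function() {
    parts <- list()
    while (!is.na(peek()) && !(peek() %in% c(",", ")"))) {
      parts[[length(parts) + 1L]] <- parse_factor()
    }
    if (length(parts) == 0L) stopf("empty term in step expression '%s'", text)
    expr_all(parts)
  }
  parse_factor <- function() {
    tok <- peek()
    if (tok == "(") {
      advance()
      inner <- parse_alt()
      if (is.na(peek()) || peek() != ")") stopf("unbalanced parentheses in '%s'", text)
      advance()
      inner
    } else if (tok %in% c(")", ",")) {
      stopf("unexpected '%s' in step expression '%s'", tok, text)
    } else {
      advance()
      expr_ident(tok)
    }
  }

  out <- parse_alt()
  if (pos <= length(toks)) stopf("trailing tokens in step expression '%s'", text)
  validate_expression(out)
  out
}

#' Serialize a step expression back to the text grammar
#'
#' @param expr an expression tree as produced by [parse_step_expression()].
#' @return a single string.
#' @export
deparse_step_expression <- function(expr) {
  validate_expression(expr)
  rec <- function(e, parent) {
    switch(e$kind,
      IDENT = e$id,
      ALL_OF = {
        s <- paste(vapply(e$children, rec, "", parent = "ALL_OF"), collapse = " ")
        if (parent == "ALL_OF") paste0("(", s, ")") else s
      },
      ANY_OF = {
        s <- paste(vapply(e$children, rec, "", parent = "ANY_OF"), collapse = ",")
        if (parent %in% c("ALL_OF", "ANY_OF")) paste0("(", s, ")") else s
      }
    )
  }
  rec(expr, parent = "TOP")
}

#' Construct a pathway database
#'
#' @param table data.frame with columns `element_id`, `function_id`,
#'   `domain_id`, `steps` (the `;`-separated step-expression string).
#' @return an object of class `pathway_db`: the definition table plus parsed
#'   step expressions, one list of steps per element.
#' @export
pathway_db <- function(table) {
  req <- c("element_id", "function_id", "domain_id", "steps")
  if (!all(req %in% names(table))) {
    stopf("pathway table needs columns %s", paste(req, collapse = ", "))
  }
  if (nrow(table) == 0L) stopf("pathway database is empty")
  if (anyDuplicated(table$element_id)) {
    stopf("duplicate element_id in pathway database: %s",
          paste(unique(table$element_id[duplicated(table$element_id)]), collapse = ", "))
  }
  steps <- lapply(as.character(table$steps), function(s) {
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0L) stopf("pathway with no steps")
    lapply(parts, parse_step_expression)
  })
  names(steps) <- table$element_id
  structure(
    list(table = as.data.frame(table, stringsAsFactors = FALSE), steps = steps),
    class = "pathway_db"
  )
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db> %d elements, %d functions, %d domains\n",
              nrow(x$table), length(unique(x$table$function_id)),
              length(unique(x$table$domain_id))))
  invisible(x)
}

expression_identifiers <- function(expr) {
  if (expr$kind == "IDENT") return(expr$id)
  unlist(lapply(expr$children, expression_identifiers), use.names = FALSE)
}

#' All identifiers required anywhere in a pathway database
#' @param db a [pathway_db()].
#' @return character vector of unique identifiers.
#' @export
required_identifiers <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  unique(unlist(lapply(db$steps, function(st) {
    unlist(lapply(st, expression_identifiers), use.names = FALSE)
  }), use.names = FALSE))
}

#' Read / write a pathway database file
#'
#' Tab-separated, one record per element with columns `element_id`,
#' `function_id`, `domain_id`, `steps`.
#'
#' @param path file path.
#' @return `read_pathway_db`: a [pathway_db()].
#' @export
read_pathway_db <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  pathway_db(tab)
}

#' @rdname read_pathway_db
#' @param db a [pathway_db()].
#' @export
write_pathway_db <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  utils::write.table(db$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic pathway database
#'
#' Builds `n_pathways` pathway elements with `steps_per_pathway` steps each.
#' Step structure is drawn to exercise the whole grammar: plain identifiers,
#' two-identifier ALL_OF steps (the half-complete case) and two-route ANY_OF
#' steps. Identifiers are unique across the database. Elements are grouped
#' into functions (4 elements per function) and two domains.
#'
#' @param n_pathways number of pathway elements.
#' @param steps_per_pathway steps per element.
#' @param seed integer seed.
#' @return a [pathway_db()].
#' @export
synthetic_pathway_db <- function(n_pathways = 40, steps_per_pathway = 4, seed = 1) {
  stopifnot(n_pathways >= 1, steps_per_pathway >= 1)
  with_seed(seed, {
    counter <- 0L
    next_ident <- function() {
      counter <<- counter + 1L
      sprintf("K%05d", counter)
    }
    make_step <- function() {
      kind <- sample(c("ident", "all2", "any2"), 1L, prob = c(0.5, 0.3, 0.2))
      switch(kind,
        ident = next_ident(),
        all2 = paste(next_ident(), next_ident()),
        any2 = paste0("(", next_ident(), ",", next_ident(), ")")
      )
    }
    steps <- vapply(seq_len(n_pathways), function(i) {
      paste(vapply(seq_len(steps_per_pathway), function(j) make_step(), ""),
            collapse = "; ")
    }, "")
    fun_of <- ceiling(seq_len(n_pathways) / 4)
    tab <- data.frame(
      element_id = sprintf("E%03d", seq_len(n_pathways)),
      function_id = sprintf("F%02d", fun_of),
      domain_id = ifelse(fun_of %% 2 == 1, "biosynthesis", "degradation"),
      steps = steps,
      stringsAsFactors = FALSE
    )
    pathway_db(tab)
  })
}
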