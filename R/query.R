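#' Domain-architecture query specification
#'
#' A query holds one or more domain patterns and a matching mode:
#' \describe{
#'   \item{ANY}{at least one pattern matches some domain on the
#'     transcript, regardless of what else is present;}
#'   \item{ALL}{every pattern matches some domain, background domains
#'     allowed;}
#'   \item{EXACT}{every pattern matches some domain AND every domain on
#'     the transcript matches some pattern — no background domain.
#'     Duplicate copies of a queried domain (tandem repeats) are never
#'     background.}
#' }
#' Patterns match a domain when they match its accession OR its short
#' name, case-insensitively; with `regex = TRUE` they are anchored full
#' regular-expression matches (write `".*DUF.*"` for containment),
#' otherwise literal equality.
#'
#' @param patterns character vector of domain patterns (may be empty when
#'   only `transcript_patterns` are used).
#' @param mode `"ANY"`, `"ALL"` or `"EXACT"` (case-insensitive).
#' @param regex treat patterns as regular expressions?
#' @param evalue_max optional e-value ceiling; domains above it are
#'   ignored by the query.
#' @param transcript_patterns optional patterns matched against
#'   transcript IDs (same regex/literal rule); when set, matching
#'   transcripts are returned and domain patterns become optional.
#' @return an object of class `query_spec`.
#' @export
query_spec <- function(patterns = character(0), mode = "ANY", regex = FALSE,
                       evalue_max = NULL, transcript_patterns = NULL) {
  mode <- toupper(mode)
  if (!mode %in% c("ANY", "ALL", "EXACT"))
    stop("mode must be one of ANY, ALL, EXACT")
  if (length(patterns) == 0L && is.null(transcript_patterns))
    stop("query needs domain patterns or transcript patterns")
  if (!is.null(evalue_max) && evalue_max < 0)
    stop("evalue_max must be >= 0")
  structure(list(patterns = as.character(patterns), mode = mode,
                 regex = isTRUE(regex), evalue_max = evalue_max,
                 transcript_patterns = transcript_patterns),
            class = "query_spec")
}

#' Compile domain patterns into a label predicate
#'
#' @param patterns character vector of patterns.
#' @param regex anchored full-match regular expressions
#'   (case-insensitive) when `TRUE`; case-insensitive literal equality
#'   when `FALSE`.
#' @return a function `(labels) -> logical matrix` with one row per
#'   pattern and one column per label; invalid regular expressions are an
#'   error naming the offending pattern.
#' @export
compile_matcher <- function(patterns, regex = FALSE) {
  patterns <- as.character(patterns)
  if (regex) {
    for (p in patterns) {
      ok <- tryCatch({ grepl(p, "x", perl = TRUE); TRUE },
                     error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok) stop("invalid regular expression pattern: '", p, "'")
    }
    anchored <- paste0("^(?:", patterns, ")$")
    function(labels) {
      m <- matrix(FALSE, nrow = length(patterns), ncol = length(labels))
      for (i in seq_along(patterns))
        m[i, ] <- grepl(anchored[i], labels, ignore.case = TRUE, perl = TRUE)
      m
    }
  } else {
    lowered <- tolower(patterns)
    function(labels) {
      ll <- tolower(labels)
      m <- matrix(FALSE, nrow = length(patterns), ncol = length(labels))
      for (i in seq_along(patterns)) m[i, ] <- ll == lowered[i]
      m
    }
  }
}

# per-domain match matrix: pattern x domain, a domain matches through its
# accession or its short name
domain_match_matrix <- function(matcher, domains) {
  acc <- vapply(domains, function(d) d$hit$domain_accession, character(1))
  nm <- vapply(domains, function(d) d$hit$domain_name, character(1))
  matcher(acc) | matcher(nm)
}

surviving_domains <- function(r, evalue_max) {
  if (is.null(evalue_max)) return(r$domains)
  Filter(function(d) d$hit$evalue <= evalue_max, r$domains)
}

#' Does a merged record satisfy a domain query?
#'
#' Applies the ANY/ALL/EXACT semantics of [query_spec] to one record's
#' surviving domains (after the optional e-value filter).
#'
#' @param r a merged record.
#' @param q a [query_spec].
#' @param matcher optional precompiled matcher from [compile_matcher]
#'   (compiled from `q` when omitted).
#' @return `TRUE` or `FALSE`.
#' @export
match_record <- function(r, q, matcher = NULL) {
  if (is.null(matcher)) matcher <- compile_matcher(q$patterns, q$regex)
  domains <- surviving_domains(r, q$evalue_max)
  if (length(q$patterns) == 0L) return(FALSE)
  if (length(domains) == 0L) return(FALSE)
  m <- domain_match_matrix(matcher, domains)
  switch(q$mode,
    ANY = any(m),
    ALL = all(apply(m, 1, any)),
    EXACT = all(apply(m, 1, any)) && all(apply(m, 2, any)))
}

#' Screen one or more merged databases
#'
#' Filters the concatenation of the given databases, preserving
#' `(genome, within-genome)` order.  When `transcript_patterns` are set, a
#' record is returned iff its transcript ID matches any of them (domain
#' patterns then optional); otherwise domain-mode filtering applies as in
#' [match_record].
#'
#' @param dbs a single `merged_db` or a list of them.
#' @param q a [query_spec].
#' @return a `merged_db` with the matching records.
#' @export
query_databases <- function(dbs, q) {
  if (inherits(dbs, "merged_db")) dbs <- list(dbs)
  matcher <- if (length(q$patterns) > 0L) compile_matcher(q$patterns, q$regex)
  tx_matcher <- if (!is.null(q$transcript_patterns))
    compile_matcher(q$transcript_patterns, q$regex)
  out <- list()
  for (db in dbs) {
    for (r in db) {
      keep <- if (!is.null(tx_matcher)) {
        any(tx_matcher(r$transcript$transcript_id))
      } else {
        match_record(r, q, matcher)
      }
      if (keep) out[[length(out) + 1L]] <- r
    }
  }
  structure(out, class = "merged_db")
}
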