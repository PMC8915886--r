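#' Tokenize raw text
#'
#' Lowercases, replaces every character that is not a lowercase letter, digit
#' or underscore with a space, and splits on whitespace. The underscore is
#' protected so that terms produced by [merge_phrases()] survive a
#' serialize/load round trip unchanged.
#'
#' @param x Character vector of raw document strings.
#' @return A list of character vectors (one token vector per input string).
#' @export
tokenize <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9_]+", " ", x)
  strsplit(trimws(x), "\\s+")
}

#' Load a corpus from plain text plus optional metadata
#'
#' Reads a UTF-8 text file with one document per line. Documents receive
#' sequential ids (`doc00001`, ...) unless metadata supplies them. Metadata is
#' a delimited table (TSV or CSV, sniffed from the extension) with a `doc_id`
#' column; it is joined by id, and any mismatch between the two files is an
#' error that names the offending ids.
#'
#' @param text_path Path to the one-document-per-line text file.
#' @param metadata_path Optional path to a TSV/CSV metadata table with a
#'   `doc_id` column whose ids must match the corpus ids exactly.
#' @return A `datm_corpus`: list with `doc_id` (character), `tokens` (list of
#'   character vectors) and `metadata` (data.frame, possibly zero-column).
#' @export
load_corpus <- function(text_path, metadata_path = NULL) {
  if (!file.exists(text_path)) stop("load_corpus: no such file: ", text_path)
  lines <- readLines(text_path, encoding = "UTF-8", warn = FALSE)
  doc_id <- sprintf("doc%05d", seq_along(lines))
  tokens <- if (length(lines)) tokenize(lines) else list()
  metadata <- data.frame(doc_id = doc_id, stringsAsFactors = FALSE)
  if (!is.null(metadata_path)) {
    if (!file.exists(metadata_path)) {
      stop("load_corpus: no such metadata file: ", metadata_path)
    }
    sep <- if (grepl("\\.csv$", metadata_path, ignore.case = TRUE)) "," else "\t"
    md <- read.delim(metadata_path, sep = sep, stringsAsFactors = FALSE,
                     comment.char = "#")
    if (!"doc_id" %in% names(md)) stop("load_corpus: metadata lacks a doc_id column")
    md$doc_id <- as.character(md$doc_id)
    missing_md <- setdiff(doc_id, md$doc_id)
    extra_md <- setdiff(md$doc_id, doc_id)
    if (length(missing_md) || length(extra_md)) {
      stop("load_corpus: doc_id mismatch between text and metadata; ",
           "missing from metadata: [",
           paste(head(missing_md, 10), collapse = ", "),
           "]; unknown in metadata: [",
           paste(head(extra_md, 10), collapse = ", "), "]")
    }
    metadata <- md[match(doc_id, md$doc_id), , drop = FALSE]
    rownames(metadata) <- NULL
  }
  new_corpus(doc_id, tokens, metadata)
}

#' Construct a corpus object from tokens already in memory
#'
#' @param doc_id Character vector of unique document ids.
#' @param tokens List of character token vectors, one per document.
#' @param metadata Optional data.frame with one row per document (a `doc_id`
#'   column is added if absent).
#' @return A `datm_corpus`.
#' @export
new_corpus <- function(doc_id, tokens, metadata = NULL) {
  if (length(doc_id) != length(tokens)) stop("new_corpus: length mismatch")
  if (anyDuplicated(doc_id)) stop("new_corpus: duplicate doc_id")
  if (is.null(metadata)) {
    metadata <- data.frame(doc_id = as.character(doc_id), stringsAsFactors = FALSE)
  }
  structure(list(doc_id = as.character(doc_id), tokens = tokens,
                 metadata = metadata),
            class = "datm_corpus")
}

#' @export
print.datm_corpus <- function(x, ...) {
  nt <- sum(lengths(x$tokens))
  cat(sprintf("<datm_corpus> %d documents, %d tokens, %d metadata columns\n",
              length(x$doc_id), nt, ncol(x$metadata) - 1L))
  invisible(x)
}

#' @export
length.datm_corpus <- function(x) length(x$doc_id)

#' Write a corpus back to the one-document-per-line format
#'
#' Inverse of [load_corpus()] up to tokenization (tokens are joined by single
#' spaces, so load-write-load is idempotent).
#'
#' @param corpus A `datm_corpus`.
#' @param text_path Output text path.
#' @param metadata_path Optional output TSV path for the metadata table.
#' @export
write_corpus <- function(corpus, text_path, metadata_path = NULL) {
  writeLines(vapply(corpus$tokens, paste, "", collapse = " "), text_path)
  if (!is.null(metadata_path)) {
    write.table(corpus$metadata, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(text_path)
}

#' Merge frequent adjacent word pairs into single terms
#'
#' Collocation detection in the word2vec/phrases style: a bigram *(a, b)* with
#' corpus counts `count(ab)`, `count(a)`, `count(b)` receives the score
#' \deqn{score(a,b) = \frac{(count(ab) - \delta)\,V}{count(a)\,count(b)}}
#' where *V* is the current number of distinct terms. Pairs scoring above
#' `threshold` are joined with `_` (left-to-right, non-overlapping). Multiple
#' passes allow multiword terms such as `everything_seemed_fine`; counts and
#' *V* are re-estimated each pass, and the procedure is a no-op once no pair
#' qualifies.
#'
#' @param corpus A `datm_corpus`.
#' @param delta Count discount; pairs rarer than `delta` can never qualify.
#' @param threshold Score cutoff (> 0).
#' @param passes Number of merge passes (>= 1).
#' @return A new `datm_corpus` with qualifying pairs joined.
#' @export
merge_phrases <- function(corpus, delta = 5, threshold = 10, passes = 2) {
  if (delta < 0) stop("merge_phrases: delta must be >= 0")
  if (threshold <= 0) stop("merge_phrases: threshold must be > 0")
  if (passes < 1) stop("merge_phrases: passes must be >= 1")
  tokens <- corpus$tokens
  for (pass in seq_len(passes)) {
    uni <- table(unlist(tokens, use.names = FALSE))
    if (!length(uni)) break
    v_size <- length(uni)
    # adjacent bigram counts over all documents
    lefts <- lapply(tokens, function(tk) if (length(tk) > 1) tk[-length(tk)] else character())
    rights <- lapply(tokens, function(tk) if (length(tk) > 1) tk[-1] else character())
    lv <- unlist(lefts, use.names = FALSE)
    rv <- unlist(rights, use.names = FALSE)
    if (!length(lv)) break
    big <- table(paste(lv, rv, sep = "\r"))
    ab <- as.numeric(big)
    parts <- strsplit(names(big), "\r", fixed = TRUE)
    a <- vapply(parts, `[`, "", 1L)
    b <- vapply(parts, `[`, "", 2L)
    score <- (ab - delta) * v_size / (as.numeric(uni[a]) * as.numeric(uni[b]))
    keep <- score > threshold
    if (!any(keep)) break
    merge_set <- paste(a[keep], b[keep], sep = "\r")
    tokens <- lapply(tokens, merge_pass_one, merge_set = merge_set)
  }
  new_corpus(corpus$doc_id, tokens, corpus$metadata)
}

# One left-to-right non-overlapping merge sweep over a token vector.
merge_pass_one <- function(tk, merge_set) {
  n <- length(tk)
  if (n < 2) return(tk)
  pair <- paste(tk[-n], tk[-1], sep = "\r")
  hit <- pair %in% merge_set
  out <- character(n)
  j <- 0L; i <- 1L
  while (i <= n) {
    if (i < n && hit[i]) {
      j <- j + 1L
      out[j] <- paste(tk[i], tk[i + 1L], sep = "_")
      i <- i + 2L
    } else {
      j <- j + 1L
      out[j] <- tk[i]
      i <- i + 1L
    }
  }
  out[seq_len(j)]
}

#' Build the vocabulary with unigram probabilities
#'
#' Terms occurring fewer than `min_count` times are dropped; unigram
#' probabilities p(w) are renormalized over the retained terms so they sum to
#' one. p(w) feeds the SIF weights of [map_context()], so the vocabulary must
#' be built on the same (post-phrase-merge) corpus that is embedded.
#'
#' @param corpus A `datm_corpus`.
#' @param min_count Minimum term count to retain (>= 1).
#' @return A `datm_vocabulary`: list with `term`, `count`, `p`, and `index`
#'   (named lookup). Terms are ordered by decreasing count, ties alphabetical.
#' @export
build_vocabulary <- function(corpus, min_count = 5) {
  if (min_count < 1) stop("build_vocabulary: min_count must be >= 1")
  tab <- table(unlist(corpus$tokens, use.names = FALSE))
  tab <- tab[tab >= min_count]
  if (!length(tab)) stop("build_vocabulary: all terms dropped (empty vocabulary)")
  ord <- order(-as.numeric(tab), names(tab))
  term <- names(tab)[ord]
  count <- as.numeric(tab)[ord]
  new_vocabulary(term, count)
}

#' Construct a vocabulary from terms and counts
#'
#' Low-level constructor (normally [build_vocabulary()] is used): unigram
#' probabilities are the normalized counts.
#'
#' @param term Character vector of unique terms.
#' @param count Positive counts, one per term.
#' @return A `datm_vocabulary`.
#' @export
new_vocabulary <- function(term, count) {
  p <- count / sum(count)
  structure(list(term = term, count = count, p = p,
                 index = setNames(seq_along(term), term)),
            class = "datm_vocabulary")
}

#' @export
print.datm_vocabulary <- function(x, ...) {
  cat(sprintf("<datm_vocabulary> %d terms, %d tokens\n",
              length(x$term), as.integer(sum(x$count))))
  invisible(x)
}

#' @export
length.datm_vocabulary <- function(x) length(x$term)

#' Write / read a vocabulary as an audit TSV (term, count, p)
#' @param vocab A `datm_vocabulary`.
#' @param path Output path.
#' @export
write_vocabulary <- function(vocab, path) {
  df <- data.frame(term = vocab$term, count = vocab$count,
                   p = formatC(vocab$p, digits = 17, format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  new_vocabulary(as.character(df$term), as.numeric(df$count))
}
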