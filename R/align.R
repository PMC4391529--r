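# Local protein alignment surface of the ortholog screen. The dynamic
# programming itself is delegated to Biostrings::pairwiseAlignment
# (type = "local", affine gaps: a gap of length L costs gapOpen +
# L * gapExtend); this file owns the identity and overlap conventions.

.substMatrix <- function(name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e))
    stop("unknown substitution matrix: ", name)
  get(name, envir = e)
}

.checkAlphabet <- function(x, alphabet, what) {
  chars <- unique(strsplit(as.character(x), "")[[1]])
  bad <- setdiff(chars, alphabet)
  if (length(bad))
    stop(what, " contains characters outside the substitution matrix ",
         "alphabet: ", paste(bad, collapse = ", "))
}

.emptyAlignment <- function(subjectId = NA_character_) {
  new("AlignmentResult", score = 0, identity = 0,
      queryStart = 0L, queryEnd = 0L, subjectStart = 0L, subjectEnd = 0L,
      overlapFraction = 0, subjectId = subjectId)
}

#' Optimal local alignment of two protein sequences
#'
#' Computes the Smith-Waterman local alignment under affine gap penalties
#' and reports the score, the identity fraction (identical aligned columns
#' divided by all alignment columns, gap columns included) and the aligned
#' spans. Scores never drop below 0; two sequences with no
#' positive-scoring residue pair yield an empty alignment of score 0.
#'
#' @param query,subject protein sequences ([Biostrings::AAString] or
#'   character scalars) over the substitution-matrix alphabet.
#' @param config a [ScreenConfig]; only the matrix and gap penalties are
#'   used here.
#' @param subjectId optional id recorded on the result.
#' @return an [AlignmentResult-class].
#' @examples
#' aln <- smithWaterman("HEAGAWGHEE", "PAWHEAE", ScreenConfig())
#' score(aln)
#' @export
smithWaterman <- function(query, subject, config = ScreenConfig(),
                          subjectId = NA_character_) {
  stopifnot(is(config, "ScreenConfig"))
  if (nchar(as.character(query)) == 0L || nchar(as.character(subject)) == 0L)
    stop("sequences must be non-empty")
  mat <- .substMatrix(config@substitutionMatrix)
  .checkAlphabet(query, rownames(mat), "query")
  .checkAlphabet(subject, colnames(mat), "subject")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(as.character(query)),
    subject = Biostrings::AAString(as.character(subject)),
    type = "local", substitutionMatrix = mat,
    gapOpening = config@gapOpen, gapExtension = config@gapExtend
  )
  sc <- BiocGenerics::score(pa)
  if (sc <= 0) return(.emptyAlignment(subjectId))
  pChars <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sChars <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ident <- sum(pChars == sChars & pChars != "-") / length(pChars)
  sRange <- Biostrings::subject(pa)
  qRange <- Biostrings::pattern(pa)
  new("AlignmentResult",
    score = sc,
    identity = ident,
    queryStart = BiocGenerics::start(qRange),
    queryEnd = BiocGenerics::end(qRange),
    subjectStart = BiocGenerics::start(sRange),
    subjectEnd = BiocGenerics::end(sRange),
    overlapFraction = BiocGenerics::width(sRange) /
      nchar(as.character(subject)),
    subjectId = subjectId
  )
}

# vectorized score of one query against a whole proteome
.scoreAgainst <- function(query, proteome, config) {
  mat <- .substMatrix(config@substitutionMatrix)
  Biostrings::pairwiseAlignment(
    pattern = proteome,
    subject = Biostrings::AAString(as.character(query)),
    type = "local", substitutionMatrix = mat,
    gapOpening = config@gapOpen, gapExtension = config@gapExtend,
    scoreOnly = TRUE
  )
}

#' Best hit of a query in a proteome
#'
#' Aligns the query against every subject, keeps subjects whose local
#' alignment reaches `minScore` and covers at least `minOverlap` of the
#' subject length, and returns the hit of highest identity. Ties on
#' identity are broken by higher score, then by lexicographically smallest
#' subject id, so the result is deterministic.
#'
#' @param query a protein sequence (character or [Biostrings::AAString]).
#' @param proteome a named [Biostrings::AAStringSet].
#' @param config a [ScreenConfig].
#' @return an [AlignmentResult-class] whose `subjectId` names the hit, or
#'   `NULL` when no subject passes both thresholds.
#' @examples
#' prot <- Biostrings::AAStringSet(c(a = "HEAGAWGHEE", b = "MKTAYIAKQR"))
#' bestHit("HEAGAWGHEE", prot, ScreenConfig(minScore = 10))
#' @export
bestHit <- function(query, proteome, config = ScreenConfig()) {
  stopifnot(is(config, "ScreenConfig"))
  if (length(proteome) == 0L) stop("proteome must be non-empty")
  if (is.null(names(proteome)) || anyNA(names(proteome)))
    stop("proteome sequences must be named")
  scores <- .scoreAgainst(query, proteome, config)
  cand <- which(scores >= config@minScore)
  if (!length(cand)) return(NULL)
  best <- NULL
  for (i in cand) {
    aln <- smithWaterman(query, as.character(proteome[[i]]), config,
                         subjectId = names(proteome)[i])
    if (aln@score < config@minScore) next
    if (aln@overlapFraction < config@minOverlap) next
    if (is.null(best) ||
        aln@identity > best@identity ||
        (aln@identity == best@identity && aln@score > best@score) ||
        (aln@identity == best@identity && aln@score == best@score &&
         aln@subjectId < best@subjectId)) {
      best <- aln
    }
  }
  best
}
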