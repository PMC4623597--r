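#' Read a UCSC chain file
#'
#' Parses pairwise-alignment chains in the UCSC chain format. The first
#' coordinate triplet of each header (`tName tSize tStrand tStart tEnd` in
#' UCSC nomenclature) is the assembly queries are expressed on (the
#' *source* here, always plus strand); the second is the assembly
#' intervals are mapped to (the *target*), whose coordinates may be on
#' the minus strand and are kept in strand coordinates as in the file.
#'
#' @param path path to a chain file.
#' @return a [ChainSet-class].
#' @examples
#' tmp <- tempfile(fileext = ".chain")
#' writeLines(c("chain 100 chr1 1000 + 0 100 chrA 2000 + 500 600 1",
#'              "100", ""), tmp)
#' readChainFile(tmp)
#' @export
readChainFile <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (line == "") { i <- i + 1L; next }
    f <- strsplit(line, "[ \t]+")[[1L]]
    if (f[1L] != "chain" || !length(f) %in% c(12L, 13L))
      stop("malformed chain header at line ", i, ": ", line)
    num <- suppressWarnings(as.numeric(f[c(2L, 4L, 6L, 7L, 9L, 11L, 12L)]))
    if (anyNA(num)) stop("non-numeric field in chain header at line ", i)
    if (any(num[-1L] < 0)) stop("negative coordinate in header at line ", i)
    if (f[5L] != "+")
      stop("source strand must be + (line ", i, ")")
    headerLine <- i
    i <- i + 1L
    size <- integer(); dt <- integer(); dq <- integer()
    repeat {
      if (i > n) stop("unterminated chain starting at line ", headerLine)
      bl <- trimws(lines[[i]])
      if (bl == "") stop("blank line inside chain block list at line ", i)
      bf <- suppressWarnings(as.numeric(strsplit(bl, "[ \t]+")[[1L]]))
      if (anyNA(bf) || !length(bf) %in% c(1L, 3L))
        stop("malformed block line at line ", i)
      if (any(bf < 0)) stop("negative field in block line at line ", i)
      if (length(bf) == 3L) {
        size <- c(size, bf[1L]); dt <- c(dt, bf[2L]); dq <- c(dq, bf[3L])
        i <- i + 1L
      } else {
        size <- c(size, bf[1L]); dt <- c(dt, 0); dq <- c(dq, 0)
        i <- i + 1L
        break
      }
    }
    ch <- tryCatch(
      new("Chain",
          score = num[1L],
          sChrom = f[3L], sSize = num[2L], sStart = num[3L], sEnd = num[4L],
          tChrom = f[8L], tSize = num[5L], tStrand = f[10L],
          tStart = num[6L], tEnd = num[7L],
          blocks = data.frame(size = size, dt = dt, dq = dq),
          id = if (length(f) == 13L) f[13L] else as.character(length(chains) + 1L)),
      error = function(e) stop("invalid chain at line ", headerLine, ": ",
                               conditionMessage(e), call. = FALSE))
    chains[[length(chains) + 1L]] <- ch
  }
  ChainSet(chains)
}

#' Write chains in UCSC chain format
#'
#' Inverse of [readChainFile()]: a parsed file writes back bit-exactly
#' (modulo blank-line normalisation, one blank line after each chain).
#'
#' @param chains a [ChainSet-class] or list of [Chain-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeChainFile <- function(chains, path) {
  if (is(chains, "ChainSet")) chains <- chains@chains
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(sprintf("chain %s %s %s + %s %s %s %s %s %s %s %s",
                       format(ch@score, scientific = FALSE),
                       ch@sChrom, format(ch@sSize, scientific = FALSE),
                       format(ch@sStart, scientific = FALSE),
                       format(ch@sEnd, scientific = FALSE),
                       ch@tChrom, format(ch@tSize, scientific = FALSE),
                       ch@tStrand,
                       format(ch@tStart, scientific = FALSE),
                       format(ch@tEnd, scientific = FALSE), ch@id), con)
    b <- ch@blocks
    n <- nrow(b)
    if (n > 1L)
      writeLines(sprintf("%d %d %d", b$size[-n], b$dt[-n], b$dq[-n]), con)
    writeLines(c(sprintf("%d", b$size[n]), ""), con)
  }
  invisible(path)
}

#' Invert chains (swap source and target assemblies)
#'
#' Produces the chain set mapping in the opposite direction, analogous
#' to UCSC `chainSwap`. For a minus-strand chain the block list is
#' reversed and the inverted chain's target (the original source) is
#' reported on the minus strand, so that inverted chains again have a
#' plus-strand source.
#'
#' @param chains a [ChainSet-class] or single [Chain-class].
#' @return the inverted [ChainSet-class] (or [Chain-class]).
#' @export
invertChains <- function(chains) {
  inv1 <- function(ch) {
    b <- ch@blocks
    n <- nrow(b)
    if (ch@tStrand == "+") {
      nb <- data.frame(size = b$size, dt = b$dq, dq = b$dt)
      nb$dt[n] <- 0L; nb$dq[n] <- 0L
      new("Chain", score = ch@score,
          sChrom = ch@tChrom, sSize = ch@tSize,
          sStart = ch@tStart, sEnd = ch@tEnd,
          tChrom = ch@sChrom, tSize = ch@sSize, tStrand = "+",
          tStart = ch@sStart, tEnd = ch@sEnd,
          blocks = nb, id = ch@id)
    } else {
      # ascending new-source (plus-strand) order reverses the blocks;
      # the gap after new block j is the gap before old block n+1-j
      ridx <- rev(seq_len(n))
      size <- b$size[ridx]
      dt <- c(rev(b$dq[-n]), 0L)
      dq <- c(rev(b$dt[-n]), 0L)
      new("Chain", score = ch@score,
          sChrom = ch@tChrom, sSize = ch@tSize,
          sStart = ch@tSize - ch@tEnd, sEnd = ch@tSize - ch@tStart,
          tChrom = ch@sChrom, tSize = ch@sSize, tStrand = "-",
          tStart = ch@sSize - ch@sEnd, tEnd = ch@sSize - ch@sStart,
          blocks = data.frame(size = size, dt = dt, dq = dq),
          id = ch@id)
    }
  }
  if (is(chains, "Chain")) return(inv1(chains))
  ChainSet(lapply(chains@chains, inv1))
}
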