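## Secondary building blocks, the junction multigraph, enumeration of
## genome-length arrangements and isoform frequency estimation.

## canonical form of a block: the lexicographically smaller of the token
## tuple and its reverse-complement traversal
.canonBlock <- function(tokens) .minByKey(tokens, reverseArrangement(tokens))

## repeat-centered windows of a token sequence: every maximal run of repeat
## units flanked by non-repeats on both sides, plus (optionally) the
## circular wrap-around windows
.repeatWindows <- function(tokens, isRep, circular = FALSE) {
  n <- length(tokens)
  if (n < 3L) return(list())
  units <- .tokenUnit(tokens)
  rep <- isRep[units]
  rep[is.na(rep)] <- FALSE
  idx <- seq_len(n)
  if (circular) {
    ## unroll so every run appears with both flanks exactly once
    tokens2 <- c(tokens, tokens)
    rep2 <- c(rep, rep)
    wins <- list()
    i <- 2L
    while (i <= n + 1L) {
      if (rep2[i] && !rep2[i - 1L]) {
        j <- i
        while (j + 1L <= 2L * n && rep2[j + 1L]) j <- j + 1L
        if (j + 1L <= 2L * n && !rep2[j + 1L])
          wins[[length(wins) + 1L]] <- tokens2[(i - 1L):(j + 1L)]
        i <- j + 1L
      } else i <- i + 1L
    }
    return(wins)
  }
  wins <- list()
  i <- 2L
  while (i <= n - 1L) {
    if (rep[i] && !rep[i - 1L]) {
      j <- i
      while (j + 1L <= n && rep[j + 1L]) j <- j + 1L
      if (j + 1L <= n && !rep[j + 1L])
        wins[[length(wins) + 1L]] <- tokens[(i - 1L):(j + 1L)]
      i <- j + 1L
    } else i <- i + 1L
  }
  wins
}

#' Extract secondary building blocks from unit paths
#'
#' A building block is an ordered, oriented run of primary units observed
#' within single long reads: every maximal window of a path centred on a
#' repeat run (the repeat with one non-repeat flank on each side) plus all
#' length-2 adjacencies.  Blocks are canonicalised (a tuple and its
#' reverse-complement traversal are one block) and counted; blocks under
#' \code{minSupport} are dropped to suppress chimeric or error paths.
#'
#' @param paths data.frame from \code{\link{unitPaths}} (ambiguous reads are
#'   excluded) or a list of token vectors.
#' @param copyNumbers named integer vector (units with copy number >= 2 are
#'   the repeats around which windows are centred).
#' @param minSupport minimum read support (default 2).
#' @return data.frame with \code{block} (comma-joined canonical tokens),
#'   \code{length} (tokens) and \code{support}, sorted by decreasing
#'   support.
#' @export
buildingBlocks <- function(paths, copyNumbers, minSupport = 2L) {
  toks <- if (is.data.frame(paths)) pathTokens(paths) else paths
  isRep <- copyNumbers >= 2L
  counts <- new.env(parent = emptyenv())
  bump <- function(tokens) {
    key <- .arrKey(.canonBlock(tokens))
    assign(key, (if (exists(key, counts)) get(key, counts) else 0L) + 1L,
           counts)
  }
  for (tk in toks) {
    n <- length(tk)
    if (n >= 2L)
      for (i in seq_len(n - 1L)) bump(tk[i:(i + 1L)])
    for (w in .repeatWindows(tk, isRep)) bump(w)
  }
  keys <- ls(counts)
  if (!length(keys))
    return(data.frame(block = character(0), length = integer(0),
                      support = integer(0), stringsAsFactors = FALSE))
  sup <- vapply(keys, get, integer(1), envir = counts)
  len <- lengths(strsplit(keys, ",", fixed = TRUE))
  out <- data.frame(block = keys, length = len, support = unname(sup),
                    stringsAsFactors = FALSE)
  out <- out[out$support >= minSupport, , drop = FALSE]
  out <- out[order(-out$support, out$block, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Junction graph

#' Build the junction multigraph
#'
#' Vertices are unit terminus anchors; each unit contributes one edge type
#' with multiplicity equal to its copy number; observed length-2 blocks form
#' the adjacency edges and blocks of length 3 or more are retained as path
#' constraints (a walk entering a repeat run from one flank must exit
#' according to some observed block).
#'
#' @param blocks data.frame from \code{\link{buildingBlocks}} (or a
#'   character vector of comma-joined blocks).
#' @param copyNumbers named integer vector of unit copy numbers.
#' @param unitLengths optional named vector of unit lengths (bp), stored for
#'   isoform construction.
#' @return object of class \code{JunctionGraph}: list with \code{units},
#'   \code{adjacency} (canonical pair keys with weights), \code{adjMap}
#'   (token -> allowed successor tokens), \code{constraints} (canonical
#'   block keys, length >= 3) and \code{unitLengths}.
#' @export
buildJunctionGraph <- function(blocks, copyNumbers, unitLengths = NULL) {
  if (is.character(blocks)) blocks <- data.frame(
    block = blocks, support = rep(1L, length(blocks)),
    stringsAsFactors = FALSE)
  toks <- strsplit(blocks$block, ",", fixed = TRUE)
  allUnits <- unique(.tokenUnit(unlist(toks)))
  bad <- setdiff(allUnits, names(copyNumbers))
  if (length(bad))
    stop("block(s) name unit(s) absent from copyNumbers: ",
         paste(bad, collapse = ", "))
  adj <- new.env(parent = emptyenv())    # canonical pair key -> weight
  succ <- new.env(parent = emptyenv())   # token -> successor tokens
  addEdge <- function(a, b, w) {
    key <- .arrKey(.canonBlock(c(a, b)))
    assign(key, (if (exists(key, adj)) get(key, adj) else 0L) + w, adj)
    for (p in unique(list(c(a, b), reverseArrangement(c(a, b))))) {
      cur <- if (exists(p[1], succ)) get(p[1], succ) else character(0)
      assign(p[1], unique(c(cur, p[2])), succ)
    }
  }
  constraints <- character(0)
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    w <- blocks$support[i]
    if (length(tk) == 2L) addEdge(tk[1], tk[2], w)
    if (length(tk) >= 3L) {
      constraints <- c(constraints, .arrKey(.canonBlock(tk)))
      for (j in seq_len(length(tk) - 1L)) addEdge(tk[j], tk[j + 1L], 0L)
    }
  }
  structure(list(units = copyNumbers,
                 adjacency = setNames(
                   vapply(ls(adj), get, integer(1), envir = adj), ls(adj)),
                 adjMap = succ,
                 constraints = unique(constraints),
                 unitLengths = unitLengths),
            class = "JunctionGraph")
}

#' @export
print.JunctionGraph <- function(x, ...) {
  cat("JunctionGraph:", length(x$units), "units (",
      sum(x$units), "instances ),", length(x$adjacency),
      "adjacencies,", length(x$constraints), "constraint block(s)\n")
  invisible(x)
}

## check every repeat-centred window of a circular walk against the
## constraint set; windows whose repeat-run content was never observed in
## any constraint are unconstrained (the repeat was too long to span)
.walkSatisfiesConstraints <- function(tokens, graph) {
  if (!length(graph$constraints)) return(TRUE)
  isRep <- graph$units >= 2L
  conRuns <- vapply(strsplit(graph$constraints, ",", fixed = TRUE),
                    function(tk) {
                      u <- .tokenUnit(tk[-c(1L, length(tk))])
                      paste(sort(u), collapse = "/")
                    }, character(1))
  for (w in .repeatWindows(tokens, isRep, circular = TRUE)) {
    runKey <- paste(sort(.tokenUnit(w[-c(1L, length(w))])), collapse = "/")
    if (!(runKey %in% conRuns)) next
    if (!(.arrKey(.canonBlock(w)) %in% graph$constraints)) return(FALSE)
  }
  TRUE
}

#' Enumerate genome-length isoform arrangements
#'
#' Backtracking enumeration of closed walks over the junction graph that use
#' every unit exactly its copy number of times, traverse only observed
#' adjacencies, and honour the block constraints (repeat phasing read out
#' from reads that span both junctions of a repeat).  Results are
#' canonicalised, deduplicated and capped at \code{maxResults}.
#'
#' @param graph a \code{JunctionGraph} from \code{\link{buildJunctionGraph}}.
#' @param unitLengths named numeric vector of unit lengths (bp); defaults to
#'   the lengths stored in the graph.
#' @param maxResults cap on the number of distinct arrangements (an
#'   attribute \code{truncated} marks a hit cap).
#' @return list of circular \code{\link{IsoformModel}}s (labels "iso1",
#'   "iso2", ...; empty list carries a \code{diagnostic} attribute naming an
#'   unsatisfiable terminus when no walk exists).
#' @export
enumerateIsoforms <- function(graph, unitLengths = NULL, maxResults = 10000L) {
  stopifnot(inherits(graph, "JunctionGraph"))
  if (is.null(unitLengths)) unitLengths <- graph$unitLengths
  if (is.null(unitLengths))
    stop("unit lengths are required (pass 'unitLengths')")
  cn <- graph$units
  unitsAll <- names(cn)
  ## tokens with no successors make the walk unsatisfiable
  succOf <- function(tok) {
    if (exists(tok, graph$adjMap)) get(tok, graph$adjMap) else character(0)
  }
  ## fix the start at a single-copy unit (every closed walk contains it)
  startUnit <- unitsAll[cn == 1L][1]
  if (is.na(startUnit)) startUnit <- unitsAll[1]
  startTok <- paste0(startUnit, "+")
  total <- sum(cn)
  results <- new.env(parent = emptyenv())
  nFound <- 0L
  truncated <- FALSE

  walk <- character(total)
  remaining <- cn
  recurse <- function(depth) {
    if (truncated) return()
    if (depth > total) {
      ## close the circle
      if (!(walk[1] %in% succOf(walk[total]))) return()
      if (!.walkSatisfiesConstraints(walk, graph)) return()
      key <- .arrKey(canonicalArrangement(walk, "circular"))
      if (!exists(key, results)) {
        if (nFound >= maxResults) { truncated <<- TRUE; return() }
        assign(key, TRUE, results)
        nFound <<- nFound + 1L
      }
      return()
    }
    prev <- walk[depth - 1L]
    for (nxt in succOf(prev)) {
      u <- .tokenUnit(nxt)
      if (is.na(remaining[u]) || remaining[u] < 1L) next
      walk[depth] <<- nxt
      remaining[u] <<- remaining[u] - 1L
      recurse(depth + 1L)
      remaining[u] <<- remaining[u] + 1L
    }
  }
  walk[1] <- startTok
  remaining[startUnit] <- remaining[startUnit] - 1L
  recurse(2L)

  keys <- ls(results)
  if (!length(keys)) {
    out <- list()
    dead <- character(0)
    for (u in unitsAll) for (s in c("+", "-")) {
      tok <- paste0(u, s)
      if (!length(succOf(tok))) dead <- c(dead, tok)
    }
    attr(out, "diagnostic") <- if (length(dead))
      paste("no closed walk; terminus with no observed adjacency:",
            paste(dead, collapse = ", "))
    else "no closed walk satisfies the adjacency and block constraints"
    return(out)
  }
  keys <- sort(keys, method = "radix")
  out <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    out[[i]] <- isoformModel(sprintf("iso%d", i),
                             strsplit(keys[i], ",", fixed = TRUE)[[1]],
                             unitLengths = unitLengths,
                             topology = "circular", canonical = FALSE)
  }
  attr(out, "truncated") <- truncated
  out
}

## ---------------------------------------------------------------------------
## Isoform frequency estimation

## occurrences of each canonical block key in a circular arrangement
.blockOccurrences <- function(tokens, keys, isRep) {
  n <- length(tokens)
  occ <- setNames(numeric(length(keys)), keys)
  pairs <- lapply(seq_len(n), function(i)
    c(tokens[i], tokens[if (i == n) 1L else i + 1L]))
  for (p in pairs) {
    k <- .arrKey(.canonBlock(p))
    if (k %in% keys) occ[k] <- occ[k] + 1
  }
  for (w in .repeatWindows(tokens, isRep, circular = TRUE)) {
    k <- .arrKey(.canonBlock(w))
    if (k %in% keys) occ[k] <- occ[k] + 1
  }
  occ
}

#' Estimate isoform frequencies from block supports
#'
#' Least-squares fit of simplex-constrained isoform frequencies to the
#' observed support fractions of the secondary building blocks.  Blocks are
#' grouped by their repeat-run content (all windows through one repeat share
#' the same read-length detectability, which therefore cancels within a
#' group) and within-group fractions are fitted, weighted by group support.
#' Length-2 blocks are used only when no longer blocks exist: around a 2x
#' repeat hinge the pairwise junction multiset is typically identical across
#' isoforms and carries no signal.
#'
#' @param isoforms list of \code{\link{IsoformModel}}s (e.g. from
#'   \code{\link{enumerateIsoforms}}).
#' @param blockSupports data.frame with \code{block} and \code{support}
#'   (from \code{\link{buildingBlocks}}).
#' @param copyNumbers named integer vector (repeat definition); defaults to
#'   the maximal multiplicity over the supplied isoforms.
#' @return list with \code{frequencies} (named by isoform label),
#'   \code{residuals} (per-block observed minus fitted fraction),
#'   \code{flagged} (TRUE when isoforms are indistinguishable by the
#'   supplied blocks, in which case frequencies are tied).
#' @export
scoreIsoforms <- function(isoforms, blockSupports, copyNumbers = NULL) {
  K <- length(isoforms)
  if (K == 0L) stop("no isoforms to score")
  labels <- vapply(isoforms, function(i) i@label, character(1))
  if (K == 1L)
    return(list(frequencies = setNames(1, labels), residuals = NULL,
                flagged = FALSE))
  if (is.null(copyNumbers)) {
    cn <- integer(0)
    for (iso in isoforms) {
      m <- table(.tokenUnit(iso@arrangement))
      for (u in names(m)) cn[u] <- max(cn[u], m[[u]], na.rm = TRUE)
    }
    copyNumbers <- cn
  }
  isRep <- copyNumbers >= 2L
  bl <- blockSupports
  long <- bl[lengths(strsplit(bl$block, ",", fixed = TRUE)) >= 3L, ,
             drop = FALSE]
  if (nrow(long)) bl <- long
  keys <- bl$block
  A <- vapply(isoforms, function(iso)
    .blockOccurrences(iso@arrangement, keys, isRep), numeric(length(keys)))
  A <- matrix(A, nrow = length(keys),
              dimnames = list(keys, labels))
  ## group rows by repeat-run content (pairs group together as "")
  runKey <- vapply(strsplit(keys, ",", fixed = TRUE), function(tk) {
    if (length(tk) < 3L) return("pair")
    paste(sort(.tokenUnit(tk[-c(1L, length(tk))])), collapse = "/")
  }, character(1))
  if (K >= 2L && all(apply(A, 1, function(r) length(unique(r)) == 1L))) {
    f <- setNames(rep(1 / K, K), labels)
    return(list(frequencies = f, residuals = NULL, flagged = TRUE))
  }
  obj <- function(theta) {
    f <- exp(c(theta, 0)); f <- f / sum(f)
    ss <- 0
    for (g in unique(runKey)) {
      i <- runKey == g
      tot <- sum(bl$support[i])
      if (tot == 0) next
      obsF <- bl$support[i] / tot
      pred <- as.vector(A[i, , drop = FALSE] %*% f)
      predTot <- sum(pred)
      if (predTot <= 0) { ss <- ss + sum(obsF^2) * tot; next }
      ss <- ss + tot * sum((obsF - pred / predTot)^2)
    }
    ss
  }
  if (K == 2L) {
    fit <- stats::optimize(function(th) obj(th), c(-12, 12))
    par <- fit$minimum
  } else {
    fit <- optim(rep(0, K - 1L), obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-10))
    par <- fit$par
  }
  f <- exp(c(par, 0)); f <- f / sum(f)
  names(f) <- labels
  ## residual report per block
  resid <- numeric(length(keys))
  for (g in unique(runKey)) {
    i <- runKey == g
    tot <- sum(bl$support[i])
    pred <- as.vector(A[i, , drop = FALSE] %*% f)
    predTot <- sum(pred)
    obsF <- if (tot > 0) bl$support[i] / tot else rep(0, sum(i))
    resid[i] <- obsF - if (predTot > 0) pred / predTot else 0
  }
  list(frequencies = f,
       residuals = data.frame(block = keys, group = runKey,
                              support = bl$support, residual = resid,
                              stringsAsFactors = FALSE),
       flagged = FALSE)
}
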