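# Lightweight SMILES molecular-graph engine.
#
# A molecule is a list with parallel atom vectors (elem, arom, charge, hcount)
# and parallel bond vectors (ba, bb, border, barom). hcount is the resolved
# hydrogen count (explicit bracket count or the implicit-valence fill).
# Aromaticity is taken as written (lowercase atoms / ':' bonds); Kekule input
# is kept Kekule. Stereochemistry is stripped at parse time by default.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ELEMS <- c("b", "c", "n", "o", "p", "s", "se", "as")

# default valence sets; charge shifts the whole set
.default_valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = c(1, 3, 5, 7), Br = c(1, 3, 5, 7), I = c(1, 3, 5, 7)
)

.new_mol <- function() {
  list(elem = character(), arom = logical(), charge = integer(),
       hcount = integer(), hexplicit = logical(),
       ba = integer(), bb = integer(), border = numeric(), barom = logical(),
       bdefault = logical())
}

.n_atoms <- function(mol) length(mol$elem)
.n_bonds <- function(mol) length(mol$ba)

.add_atom <- function(mol, elem, arom, charge = 0L, hcount = NA_integer_) {
  mol$elem <- c(mol$elem, elem)
  mol$arom <- c(mol$arom, arom)
  mol$charge <- c(mol$charge, as.integer(charge))
  mol$hcount <- c(mol$hcount, as.integer(hcount))
  mol$hexplicit <- c(mol$hexplicit, !is.na(hcount))
  mol
}

.add_bond <- function(mol, a, b, order, arom, default = FALSE) {
  mol$ba <- c(mol$ba, as.integer(a)); mol$bb <- c(mol$bb, as.integer(b))
  mol$border <- c(mol$border, order)
  mol$barom <- c(mol$barom, arom)
  mol$bdefault <- c(mol$bdefault, default)
  mol
}

# --- parsing ---------------------------------------------------------------

.parse_bracket <- function(body) {
  # body: contents between [ ], stereo markers dropped
  orig <- body
  body <- sub("^[0-9]+", "", body)                      # isotope ignored
  m <- regmatches(body, regexpr("^([A-Z][a-z]?|as|se|[bcnops]|\\*)", body))
  if (length(m) == 0 || !nzchar(m)) stop("bad bracket atom [", orig, "]")
  elem_raw <- m
  body <- substring(body, nchar(m) + 1L)
  arom <- elem_raw %in% AROMATIC_ELEMS
  elem <- if (arom) paste0(toupper(substring(elem_raw, 1, 1)),
                           substring(elem_raw, 2)) else elem_raw
  body <- gsub("@+(TH|AL|SP|TB|OH)?[0-9]*", "", body)   # chirality stripped
  hcount <- 0L
  hm <- regmatches(body, regexpr("H[0-9]*", body))
  if (length(hm) == 1 && nzchar(hm)) {
    hcount <- if (nchar(hm) == 1) 1L else as.integer(substring(hm, 2))
    body <- sub("H[0-9]*", "", body)
  }
  charge <- 0L
  cm <- regmatches(body, regexpr("[+-][0-9]*[+-]*", body))
  if (length(cm) == 1 && nzchar(cm)) {
    sign <- if (substring(cm, 1, 1) == "+") 1L else -1L
    digits <- regmatches(cm, regexpr("[0-9]+", cm))
    charge <- if (length(digits) == 1 && nzchar(digits)) sign * as.integer(digits)
              else sign * nchar(gsub("[^+-]", "", cm))
    body <- sub("[+-][0-9]*[+-]*", "", body)
  }
  body <- sub(":[0-9]+", "", body)                      # atom map ignored
  if (nzchar(body)) stop("bad bracket atom [", orig, "]")
  list(elem = elem, arom = arom, charge = charge, hcount = hcount)
}

#' @keywords internal
smi_parse <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) || !nzchar(smiles))
    stop("unparseable: empty SMILES")
  mol <- .new_mol()
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  i <- 1L; n <- length(chars)
  prev <- 0L                       # index of previous atom (0 = none)
  stack <- integer()               # branch stack
  pend_order <- NA_real_           # pending explicit bond
  pend_arom <- FALSE
  ring_open <- list()              # label -> list(atom, order, arom, explicit)
  bond_to <- function(mol, a, b) {
    if (a == 0L) stop("unparseable: bond with no previous atom")
    if (is.na(pend_order)) .add_bond(mol, a, b, 1, FALSE, default = TRUE)
    else .add_bond(mol, a, b, pend_order, pend_arom)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unparseable: unclosed bracket")
      at <- .parse_bracket(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      mol <- .add_atom(mol, at$elem, at$arom, at$charge, at$hcount)
      idx <- .n_atoms(mol)
      if (prev != 0L) mol <- bond_to(mol, prev, idx)
      pend_order <- NA_real_; pend_arom <- FALSE
      prev <- idx
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      mol <- .add_atom(mol, paste0(ch, chars[i + 1L]), FALSE)
      idx <- .n_atoms(mol)
      if (prev != 0L) mol <- bond_to(mol, prev, idx)
      pend_order <- NA_real_; pend_arom <- FALSE
      prev <- idx
      i <- i + 2L
    } else if (ch %in% ORGANIC_SUBSET) {
      mol <- .add_atom(mol, ch, FALSE)
      idx <- .n_atoms(mol)
      if (prev != 0L) mol <- bond_to(mol, prev, idx)
      pend_order <- NA_real_; pend_arom <- FALSE
      prev <- idx
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      mol <- .add_atom(mol, toupper(ch), TRUE)
      idx <- .n_atoms(mol)
      if (prev != 0L) mol <- bond_to(mol, prev, idx)
      pend_order <- NA_real_; pend_arom <- FALSE
      prev <- idx
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pend_order <- 1; pend_arom <- FALSE; i <- i + 1L
    } else if (ch == "=") {
      pend_order <- 2; pend_arom <- FALSE; i <- i + 1L
    } else if (ch == "#") {
      pend_order <- 3; pend_arom <- FALSE; i <- i + 1L
    } else if (ch == ":") {
      pend_order <- 1; pend_arom <- TRUE; i <- i + 1L
    } else if (ch == "(") {
      if (prev == 0L) stop("unparseable: branch before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) stop("unparseable: unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
          stop("unparseable: bad %nn ring closure")
        lab <- paste0("%", chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else { lab <- ch; i <- i + 1L }
      if (prev == 0L) stop("unparseable: ring closure before any atom")
      if (!is.null(ring_open[[lab]])) {
        op <- ring_open[[lab]]
        if (op$atom == prev) stop("unparseable: self ring closure")
        explicit_here <- !is.na(pend_order)
        if (op$explicit && explicit_here &&
            (op$order != pend_order || op$arom != pend_arom))
          stop("unparseable: conflicting ring-closure bonds")
        if (op$explicit) { o <- op$order; a <- op$arom; d <- FALSE }
        else if (explicit_here) { o <- pend_order; a <- pend_arom; d <- FALSE }
        else { o <- 1; a <- FALSE; d <- TRUE }
        mol <- .add_bond(mol, op$atom, prev, o, a, default = d)
        ring_open[[lab]] <- NULL
      } else {
        ring_open[[lab]] <- list(atom = prev, order = if (is.na(pend_order)) 1 else pend_order,
                                 arom = pend_arom, explicit = !is.na(pend_order))
      }
      pend_order <- NA_real_; pend_arom <- FALSE
    } else if (ch == ".") {
      prev <- 0L; pend_order <- NA_real_; pend_arom <- FALSE; i <- i + 1L
    } else {
      stop("unparseable: invalid character '", ch, "'")
    }
  }
  if (length(ring_open) > 0) stop("unparseable: unmatched ring bonds")
  if (length(stack) > 0) stop("unparseable: unbalanced '('")
  if (.n_atoms(mol) == 0) stop("unparseable: no atoms")
  mol <- .resolve_bonds(mol)
  mol$hcount <- .implicit_h(mol)
  bad <- .check_valence(mol)
  if (!is.null(bad)) stop("unparseable: ", bad)
  bad <- .check_aromatic(mol)
  if (!is.null(bad)) stop("unparseable: ", bad)
  class(mol) <- "mfmol"
  mol
}

# default-order bonds between two aromatic atoms are aromatic iff they are
# ring bonds (biphenyl bridge stays single; benzene edges become aromatic)
.resolve_bonds <- function(mol) {
  if (.n_bonds(mol) == 0) return(mol)
  ringb <- .ring_bond_flags(mol)
  cand <- mol$bdefault & mol$arom[mol$ba] & mol$arom[mol$bb] & ringb
  mol$barom[cand] <- TRUE
  mol$border[mol$barom] <- 1
  mol
}

# bonds that lie on a cycle (non-bridges), via DFS low-link
.ring_bond_flags <- function(mol) {
  n <- .n_atoms(mol); m <- .n_bonds(mol)
  if (m == 0) return(logical(0))
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    adj[[mol$ba[k]]] <- c(adj[[mol$ba[k]]], k)
    adj[[mol$bb[k]]] <- c(adj[[mol$bb[k]]], k)
  }
  other <- function(k, a) if (mol$ba[k] == a) mol$bb[k] else mol$ba[k]
  disc <- rep(0L, n); low <- rep(0L, n); timer <- 0L
  is_bridge <- rep(FALSE, m)
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    # iterative DFS
    stk <- list(list(v = root, pe = 0L, ei = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stk) > 0) {
      fr <- stk[[length(stk)]]
      v <- fr$v
      if (fr$ei <= length(adj[[v]])) {
        k <- adj[[v]][fr$ei]
        stk[[length(stk)]]$ei <- fr$ei + 1L
        if (k == fr$pe) next
        u <- other(k, v)
        if (disc[u] == 0L) {
          timer <- timer + 1L; disc[u] <- low[u] <- timer
          stk[[length(stk) + 1L]] <- list(v = u, pe = k, ei = 1L)
        } else low[v] <- min(low[v], disc[u])
      } else {
        stk[[length(stk)]] <- NULL
        if (length(stk) > 0) {
          p <- stk[[length(stk)]]$v
          low[p] <- min(low[p], low[v])
          if (low[v] > disc[p]) is_bridge[fr$pe] <- TRUE
        }
      }
    }
  }
  !is_bridge
}

# pi-electron role of an aromatic atom: 1 = contributes a Kekule double bond
# (adds 1 to valence), 2 = donates a lone pair (adds 0)
.pi_electrons <- function(mol) {
  n <- .n_atoms(mol)
  deg <- .degree(mol)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!mol$arom[i]) next
    conn <- deg[i] + ifelse(is.na(mol$hcount[i]), 0L, mol$hcount[i])
    e <- mol$elem[i]; q <- mol$charge[i]
    out[i] <- if (e %in% c("C", "B")) {
      if (e == "C" && q == -1L) 2L else 1L
    } else if (e %in% c("N", "P", "As")) {
      if (conn >= 3L && q <= 0L) 2L else 1L
    } else if (e %in% c("O", "S", "Se")) {
      if (q > 0L) 1L else 2L
    } else 1L
  }
  out
}

.degree <- function(mol) {
  n <- .n_atoms(mol)
  d <- integer(n)
  if (.n_bonds(mol) > 0) {
    t1 <- tabulate(mol$ba, n); t2 <- tabulate(mol$bb, n)
    d <- t1 + t2
  }
  d
}

# sum of bond orders seen by each atom, aromatic bonds counted as 1
.bondsum <- function(mol) {
  n <- .n_atoms(mol)
  s <- numeric(n)
  for (k in seq_len(.n_bonds(mol))) {
    o <- if (mol$barom[k]) 1 else mol$border[k]
    s[mol$ba[k]] <- s[mol$ba[k]] + o
    s[mol$bb[k]] <- s[mol$bb[k]] + o
  }
  s
}

.implicit_h <- function(mol) {
  n <- .n_atoms(mol)
  bs <- .bondsum(mol)
  deg <- .degree(mol)
  h <- mol$hcount
  for (i in seq_len(n)) {
    if (!is.na(h[i])) next                     # bracket atom: explicit (or 0)
    e <- mol$elem[i]
    if (mol$arom[i]) {
      h[i] <- switch(e,
        C = max(0L, 4L - as.integer(deg[i]) - 1L),
        B = max(0L, 3L - as.integer(deg[i]) - 1L),
        N = 0L, P = 0L,
        O = 0L, S = 0L, 0L)
    } else {
      vals <- .default_valences[[e]]
      if (is.null(vals)) { h[i] <- 0L; next }
      fit <- vals[vals >= bs[i]]
      h[i] <- if (length(fit) == 0) 0L else as.integer(min(fit) - bs[i])
    }
  }
  as.integer(h)
}

.check_valence <- function(mol) {
  bs <- .bondsum(mol)
  pie <- .pi_electrons(mol)
  for (i in seq_len(.n_atoms(mol))) {
    e <- mol$elem[i]
    vals <- .default_valences[[e]]
    if (is.null(vals)) next                    # uncommon element: not checked
    vals <- vals + mol$charge[i]
    vals <- vals[vals >= 0]
    if (length(vals) == 0) return(sprintf("impossible charge on %s", e))
    used <- bs[i] + mol$hcount[i] + if (mol$arom[i] && !is.na(pie[i]) && pie[i] == 1L) 1L else 0L
    if (used > max(vals)) return(sprintf("valence %s on atom %d (%s)", used, i, e))
  }
  NULL
}

# every aromatic atom must sit in a ring made of aromatic atoms and aromatic
# bonds; isolated (non-fused) aromatic rings must satisfy Huckel 4n+2
.check_aromatic <- function(mol) {
  ar <- which(mol$arom)
  if (length(ar) == 0) return(NULL)
  rings <- .candidate_rings(mol)
  arom_rings <- Filter(function(r) all(mol$arom[r]), rings)
  covered <- unique(unlist(arom_rings))
  if (!all(ar %in% covered)) return("aromatic atom outside an aromatic ring")
  if (length(arom_rings) > 0) {
    pie <- .pi_electrons(mol)
    counts <- table(unlist(arom_rings))
    fused_atoms <- as.integer(names(counts)[counts > 1])
    for (r in arom_rings) {
      if (any(r %in% fused_atoms)) next        # fused systems: skip Huckel
      ne <- sum(pie[r])
      if (ne %% 4 != 2) return(sprintf("aromatic ring fails Huckel rule (%d pi electrons)", ne))
    }
  }
  NULL
}

# one shortest cycle through each ring bond (deduplicated atom sets)
.candidate_rings <- function(mol) {
  m <- .n_bonds(mol)
  if (m == 0) return(list())
  ringb <- .ring_bond_flags(mol)
  n <- .n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    adj[[mol$ba[k]]] <- rbind(adj[[mol$ba[k]]], c(k, mol$bb[k]))
    adj[[mol$bb[k]]] <- rbind(adj[[mol$bb[k]]], c(k, mol$ba[k]))
  }
  rings <- list(); seen <- character()
  for (k in which(ringb)) {
    s <- mol$ba[k]; t <- mol$bb[k]
    # BFS shortest path s -> t avoiding bond k
    prevb <- rep(NA_integer_, n); preva <- rep(NA_integer_, n)
    visited <- rep(FALSE, n); visited[s] <- TRUE
    queue <- s; found <- FALSE
    while (length(queue) > 0 && !found) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      for (r in seq_len(NROW(nb))) {
        kk <- nb[r, 1]; u <- nb[r, 2]
        if (kk == k || visited[u]) next
        visited[u] <- TRUE; preva[u] <- v; prevb[u] <- kk
        if (u == t) { found <- TRUE; break }
        queue <- c(queue, u)
      }
    }
    if (!found) next
    path <- t
    while (path[1] != s) path <- c(preva[path[1]], path)
    key <- paste(sort(path), collapse = ",")
    if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- path }
  }
  rings
}

# smallest set of smallest rings (greedy over candidate cycles); the SSSR
# *count* is the cyclomatic number, exact regardless of the greedy choice
.sssr <- function(mol) {
  rings <- .candidate_rings(mol)
  if (length(rings) == 0) return(list())
  target <- .ring_count(mol)
  rings <- rings[order(vapply(rings, length, integer(1)))]
  chosen <- list()
  edge_key <- function(r) {
    rr <- c(r, r[1])
    sort(vapply(seq_along(r), function(i) paste(sort(c(rr[i], rr[i + 1])), collapse = "-"), character(1)))
  }
  covered <- character()
  for (r in rings) {
    if (length(chosen) >= target) break
    ek <- edge_key(r)
    if (any(!(ek %in% covered))) {
      chosen[[length(chosen) + 1L]] <- r
      covered <- union(covered, ek)
    }
  }
  chosen
}

.ring_count <- function(mol) {
  n <- .n_atoms(mol); m <- .n_bonds(mol)
  comp <- .components(mol)
  m - n + length(unique(comp))
}

.components <- function(mol) {
  n <- .n_atoms(mol)
  comp <- rep(0L, n); cur <- 0L
  adj <- .adjlist(mol)
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]$atom) if (comp[u] == 0L) { comp[u] <- cur; queue <- c(queue, u) }
    }
  }
  comp
}

.adjlist <- function(mol) {
  n <- .n_atoms(mol)
  adj <- replicate(n, list(atom = integer(), bond = integer()), simplify = FALSE)
  for (k in seq_len(.n_bonds(mol))) {
    a <- mol$ba[k]; b <- mol$bb[k]
    adj[[a]]$atom <- c(adj[[a]]$atom, b); adj[[a]]$bond <- c(adj[[a]]$bond, k)
    adj[[b]]$atom <- c(adj[[b]]$atom, a); adj[[b]]$bond <- c(adj[[b]]$bond, k)
  }
  adj
}

# --- writing ---------------------------------------------------------------

# writes one connected molecule (or multi-fragment: fragments sorted) given a
# total order 'ranks' (lower rank = earlier start / earlier neighbor)
smi_write <- function(mol, ranks = NULL) {
  n <- .n_atoms(mol)
  if (is.null(ranks)) ranks <- seq_len(n)
  comp <- .components(mol)
  frags <- character(0)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    frags <- c(frags, .write_fragment(mol, idx, ranks))
  }
  paste(sort(frags), collapse = ".")
}

.write_fragment <- function(mol, idx, ranks) {
  adj <- .adjlist(mol)
  ringb <- .ring_bond_flags(mol)
  start <- idx[which.min(ranks[idx])]
  n <- .n_atoms(mol)
  # DFS to classify tree vs ring-closure bonds
  tree_bond <- rep(FALSE, .n_bonds(mol))
  closure_at <- replicate(n, integer(), simplify = FALSE)
  order_children <- function(v, exclude_bond) {
    nb <- adj[[v]]
    keep <- nb$bond != exclude_bond
    at <- nb$atom[keep]; bo <- nb$bond[keep]
    o <- order(ranks[at])
    list(atom = at[o], bond = bo[o])
  }
  # iterative DFS marking tree bonds and closures
  visited2 <- rep(FALSE, n)
  visited2[start] <- TRUE
  stack_frames <- list(list(v = start, pb = 0L, ch = order_children(start, 0L), i = 1L))
  while (length(stack_frames) > 0) {
    fr <- stack_frames[[length(stack_frames)]]
    if (fr$i <= length(fr$ch$atom)) {
      u <- fr$ch$atom[fr$i]; k <- fr$ch$bond[fr$i]
      stack_frames[[length(stack_frames)]]$i <- fr$i + 1L
      if (!visited2[u]) {
        visited2[u] <- TRUE
        tree_bond[k] <- TRUE
        stack_frames[[length(stack_frames) + 1L]] <-
          list(v = u, pb = k, ch = order_children(u, k), i = 1L)
      } else if (!tree_bond[k] && !(k %in% closure_at[[fr$v]]) && !(k %in% closure_at[[u]])) {
        closure_at[[fr$v]] <- c(closure_at[[fr$v]], k)
        closure_at[[u]] <- c(closure_at[[u]], k)
      }
    } else stack_frames[[length(stack_frames)]] <- NULL
  }
  # emit
  digit_of <- list()   # bond k -> label
  free <- 1L
  used_digits <- integer(0)
  next_label <- function() {
    d <- 1L
    while (d %in% used_digits) d <- d + 1L
    d
  }
  bond_sym <- function(k, parent_arom_ok = TRUE) {
    if (mol$barom[k]) return("")
    o <- mol$border[k]
    if (o == 2) return("=")
    if (o == 3) return("#")
    # single bond: explicit '-' needed when both ends aromatic and it is a
    # ring bond (else reparse would make it aromatic)
    if (mol$arom[mol$ba[k]] && mol$arom[mol$bb[k]] && ringb[k]) return("-")
    ""
  }
  atom_str <- function(i) {
    e <- mol$elem[i]
    sym <- if (mol$arom[i]) tolower(e) else e
    needs_bracket <- mol$charge[i] != 0L || !(e %in% ORGANIC_SUBSET)
    if (!needs_bracket) {
      # would the parser's implicit-H rule reproduce hcount?
      imp <- {
        tmp <- mol; tmp$hcount[i] <- NA_integer_
        .implicit_h(tmp)[i]
      }
      if (imp != mol$hcount[i]) needs_bracket <- TRUE
    }
    if (!needs_bracket) return(sym)
    h <- mol$hcount[i]
    hstr <- if (h == 0) "" else if (h == 1) "H" else paste0("H", h)
    q <- mol$charge[i]
    qstr <- if (q == 0) "" else if (q == 1) "+" else if (q == -1) "-"
            else if (q > 1) paste0("+", q) else paste0("-", abs(q))
    paste0("[", sym, hstr, qstr, "]")
  }
  out <- character(0)
  emit_atom <- function(v) {
    s <- atom_str(v)
    # ring closure digits at this atom, ordered by rank of the other end
    ks <- closure_at[[v]]
    if (length(ks) > 0) {
      others <- vapply(ks, function(k) if (mol$ba[k] == v) mol$bb[k] else mol$ba[k], integer(1))
      ks <- ks[order(ranks[others])]
      for (k in ks) {
        key <- as.character(k)
        if (is.null(digit_of[[key]])) {
          d <- next_label()
          used_digits <<- c(used_digits, d)
          digit_of[[key]] <<- d
          lab <- if (d > 9) sprintf("%%%02d", d) else as.character(d)
          s <- paste0(s, bond_sym(k), lab)
        } else {
          d <- digit_of[[key]]
          used_digits <<- setdiff(used_digits, d)
          lab <- if (d > 9) sprintf("%%%02d", d) else as.character(d)
          s <- paste0(s, bond_sym(k), lab)
        }
      }
    }
    s
  }
  rec <- function(v, via_bond) {
    piece <- if (via_bond == 0L) emit_atom(v) else paste0(bond_sym(via_bond), emit_atom(v))
    ch <- order_children(v, via_bond)
    segs <- character(0)
    for (j in seq_along(ch$atom)) {
      k <- ch$bond[j]; u <- ch$atom[j]
      if (tree_bond[k] && parent_bond[u] == k) segs <- c(segs, rec(u, k))
    }
    if (length(segs) == 0) return(piece)
    if (length(segs) == 1) return(paste0(piece, segs))
    paste0(piece, paste0(vapply(segs[-length(segs)], function(x) paste0("(", x, ")"), character(1)), collapse = ""), segs[length(segs)])
  }
  # orient tree bonds (parent map) by BFS from the start atom
  parent_bond <- rep(0L, n)
  po_visited <- rep(FALSE, n); po_visited[start] <- TRUE
  queue <- start
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]
    for (j in seq_along(nb$atom)) {
      k <- nb$bond[j]; u <- nb$atom[j]
      if (tree_bond[k] && !po_visited[u]) {
        po_visited[u] <- TRUE; parent_bond[u] <- k; queue <- c(queue, u)
      }
    }
  }
  old_depth <- getOption("expressions")
  on.exit(options(expressions = old_depth), add = TRUE)
  options(expressions = 500000)
  rec(start, 0L)
}

# --- canonical ranks -------------------------------------------------------

.initial_invariants <- function(mol) {
  deg <- .degree(mol)
  ringb <- .ring_bond_flags(mol)
  nring <- integer(.n_atoms(mol))
  for (k in which(ringb)) {
    nring[mol$ba[k]] <- nring[mol$ba[k]] + 1L
    nring[mol$bb[k]] <- nring[mol$bb[k]] + 1L
  }
  sprintf("%s|%d|%d|%+d|%d|%d", mol$elem, as.integer(mol$arom), deg,
          mol$charge, mol$hcount, nring)
}

.refine_ranks <- function(mol, ranks, adj) {
  n <- .n_atoms(mol)
  repeat {
    keys <- character(n)
    for (i in seq_len(n)) {
      nb <- adj[[i]]
      if (length(nb$atom) == 0) { keys[i] <- sprintf("%06d|", ranks[i]); next }
      codes <- vapply(seq_along(nb$atom), function(j) {
        k <- nb$bond[j]
        bc <- if (mol$barom[k]) 4 else mol$border[k]
        sprintf("%d:%06d", bc, ranks[nb$atom[j]])
      }, character(1))
      keys[i] <- sprintf("%06d|%s", ranks[i], paste(sort(codes), collapse = ","))
    }
    new_ranks <- match(keys, sort(unique(keys)))
    if (length(unique(new_ranks)) == length(unique(ranks)) && all(new_ranks == ranks)) break
    if (length(unique(new_ranks)) == length(unique(ranks))) { ranks <- new_ranks; break }
    ranks <- new_ranks
  }
  ranks
}

#' @keywords internal
canonical_ranks <- function(mol) {
  n <- .n_atoms(mol)
  adj <- .adjlist(mol)
  inv <- .initial_invariants(mol)
  ranks <- match(inv, sort(unique(inv)))
  ranks <- .refine_ranks(mol, ranks, adj)
  budget <- new.env(); budget$left <- 64L
  .break_ties(mol, ranks, adj, budget)
}

.break_ties <- function(mol, ranks, adj, budget) {
  n <- .n_atoms(mol)
  if (length(unique(ranks)) == n) return(ranks)
  tab <- table(ranks)
  tied <- as.integer(names(tab)[tab > 1])
  cls <- which(ranks == min(tied))
  if (budget$left <= 0) cls <- cls[1]
  best <- NULL; best_smi <- NULL
  for (a in cls) {
    budget$left <- budget$left - 1L
    r2 <- ranks * 2L
    r2[a] <- r2[a] - 1L
    r2 <- match(r2, sort(unique(r2)))
    r2 <- .refine_ranks(mol, r2, adj)
    r2 <- .break_ties(mol, r2, adj, budget)
    smi <- smi_write(mol, r2)
    if (is.null(best_smi) || smi < best_smi) { best_smi <- smi; best <- r2 }
    if (budget$left <= 0) break
  }
  best
}

#' Canonical SMILES of a parsed molecule
#' @keywords internal
smi_canonical <- function(mol) {
  if (is.character(mol)) mol <- smi_parse(mol)
  smi_write(mol, canonical_ranks(mol))
}
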