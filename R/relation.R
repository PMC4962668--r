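# Intra-sentence CID relation extraction: candidate generation over
# co-occurring chemical/disease mention pairs, a large dependency-based
# feature set (five families), and a linear L2-regularized hinge-loss
# classifier. Predictions are aggregated to abstract-level id pairs.

#' Candidate chemical-disease pairs of a document
#'
#' One candidate per (chemical mention, disease mention) pair co-occurring
#' in a sentence (coreference-propagated mentions included), deduplicated by
#' sentence and spans.
#'
#' @param doc a `cid_document`.
#' @return data.frame with mention row indices `chem`, `dis` and
#'   `sentence_index`.
#' @export
candidate_pairs <- function(doc) {
  m <- doc$mentions
  out <- data.frame(chem = integer(), dis = integer(), sentence_index = integer())
  if (!nrow(m)) return(out)
  sent <- vapply(m$start, function(s) sentence_of_offset(doc, s), integer(1))
  for (k in unique(sent[!is.na(sent)])) {
    chems <- which(sent == k & m$type == "Chemical")
    diss <- which(sent == k & m$type == "Disease")
    if (!length(chems) || !length(diss)) next
    grid <- expand.grid(chem = chems, dis = diss)
    out <- rbind(out, data.frame(grid, sentence_index = k))
  }
  if (nrow(out)) {
    key <- paste(out$sentence_index, m$start[out$chem], m$end[out$chem],
                 m$start[out$dis], m$end[out$dis])
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Shortest dependency path between two tokens
#'
#' Breadth-first search over the sentence's dependency arcs treated as
#' undirected, recording each arc's label and direction. Ties among equal
#' length paths are broken toward the lexicographically smallest token-index
#' sequence (neighbors are expanded in ascending index order and the first
#' parent found is kept).
#'
#' @param sentence a `cid_sentence` with a parse attached.
#' @param a,b token indices.
#' @return `NULL` when no path exists, otherwise a list with `nodes`
#'   (token index sequence from `a` to `b`) and `arcs` (data.frame with
#'   `label` and `dir`, `"up"` = dependent-to-head).
#' @export
shortest_dependency_path <- function(sentence, a, b) {
  n <- nrow(sentence$tokens)
  stopifnot(a >= 1L, a <= n, b >= 1L, b <= n)
  if (a == b) {
    return(list(nodes = a, arcs = data.frame(label = character(),
                                             dir = character())))
  }
  deps <- sentence$deps
  deps <- deps[deps$head >= 1L & deps$head <= n, , drop = FALSE]
  adj <- vector("list", n)
  for (r in seq_len(nrow(deps))) {
    h <- deps$head[r]; d <- deps$dep[r]; lab <- deps$label[r]
    adj[[h]] <- rbind(adj[[h]], data.frame(to = d, label = lab, dir = "down"))
    adj[[d]] <- rbind(adj[[d]], data.frame(to = h, label = lab, dir = "up"))
  }
  parent <- rep(NA_integer_, n); plab <- character(n); pdir <- character(n)
  visited <- rep(FALSE, n); visited[a] <- TRUE
  queue <- a
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur == b) break
    nb <- adj[[cur]]
    if (is.null(nb)) next
    nb <- nb[order(nb$to), , drop = FALSE]
    for (r in seq_len(nrow(nb))) {
      t <- nb$to[r]
      if (visited[t]) next
      visited[t] <- TRUE
      parent[t] <- cur; plab[t] <- nb$label[r]; pdir[t] <- nb$dir[r]
      queue <- c(queue, t)
    }
  }
  if (!visited[b]) return(NULL)
  nodes <- b; labs <- character(); dirs <- character()
  while (nodes[1] != a) {
    p <- parent[nodes[1]]
    labs <- c(plab[nodes[1]], labs); dirs <- c(pdir[nodes[1]], dirs)
    nodes <- c(p, nodes)
  }
  # direction was recorded walking from a toward b already
  list(nodes = nodes, arcs = data.frame(label = labs, dir = dirs,
                                        stringsAsFactors = FALSE))
}

# syntactic head token of a mention: the token whose head lies outside the
# span (or the root); falls back to the last token of the span
mention_head_token <- function(doc, mention_row) {
  m <- doc$mentions[mention_row, ]
  k <- sentence_of_offset(doc, m$start)
  sent <- doc$sentences[[k]]
  idx <- tokens_in_span(sent, m$start, m$end)
  if (!length(idx)) return(list(sentence_index = k, token = NA_integer_))
  head_of <- rep(NA_integer_, nrow(sent$tokens))
  if (nrow(sent$deps)) head_of[sent$deps$dep] <- sent$deps$head
  h <- idx[!(head_of[idx] %in% idx)]
  list(sentence_index = k, token = if (length(h)) h[1] else idx[length(idx)])
}

.ngrams <- function(x, nmin, nmax, sep = "_") {
  out <- character()
  L <- length(x)
  for (n in nmin:nmax) {
    if (n > L) break
    for (i in seq_len(L - n + 1L)) {
      out <- c(out, paste(x[i:(i + n - 1L)], collapse = sep))
    }
  }
  out
}

.char_ngrams <- function(word, nmin, nmax) {
  ch <- strsplit(word, "")[[1]]
  .ngrams(ch, nmin, min(nmax, length(ch)), sep = "")
}

#' Relation feature extraction for one candidate pair
#'
#' Emits the union of five namespaced feature families: (1) `tok:` token
#' features of each entity head (word, stem, shape, character n-grams, POS);
#' (2) `nbr:` neighboring-token features from 2-step dependency paths around
#' each head; (3) `win:` token n-grams in a +/-3 window around each entity;
#' (4) `pair:` word/dependency/mixed n-grams over the window spanning the
#' pair; (5) `sdp:` shortest-dependency-path features (bucketed length,
#' word and dependency-label n-grams along the path, governor-dependent
#' word pairs, edge walks and vertex walks with their sub-structures).
#' Mention tokens are blinded to `CHEM`/`DIS` placeholders in families 2-5.
#' Families 2 and 5 are omitted when the sentence has no parse.
#'
#' @param doc a `cid_document`.
#' @param chem,dis mention row indices of the candidate.
#' @param config named logical flags `token`, `neighbor`, `window`, `pair`,
#'   `path`; missing flags default to TRUE.
#' @return named numeric vector of feature counts.
#' @export
extract_relation_features <- function(doc, chem, dis, config = NULL) {
  on <- function(flag) is.null(config) || is.null(config[[flag]]) || isTRUE(config[[flag]])
  hc <- mention_head_token(doc, chem)
  hd <- mention_head_token(doc, dis)
  stopifnot(hc$sentence_index == hd$sentence_index)
  sent <- doc$sentences[[hc$sentence_index]]
  tok <- sent$tokens
  n <- nrow(tok)
  has_parse <- nrow(sent$deps) > 0L

  m <- doc$mentions
  blind <- tolower(tok$text)
  for (row in c(chem, dis)) {
    idx <- tokens_in_span(sent, m$start[row], m$end[row])
    blind[idx] <- if (m$type[row] == "Chemical") "CHEM" else "DIS"
  }

  feats <- character()
  heads <- c(chem = hc$token, dis = hd$token)

  if (on("token")) {
    for (nm in names(heads)) {
      i <- heads[[nm]]
      if (is.na(i)) next
      w <- tok$text[i]; lw <- tolower(w)
      feats <- c(feats,
                 paste0("tok:", nm, ":w:", lw),
                 paste0("tok:", nm, ":stem:", tok$stem[i]),
                 paste0("tok:", nm, ":pos:", tok$pos[i]),
                 paste0("tok:", nm, ":sh:", paste0(
                   ifelse(grepl("^[A-Z]", w), "C", "c"),
                   ifelse(grepl("[0-9]", w), "d", "_"),
                   ifelse(i == 1L, "F", "_"))),
                 paste0("tok:", nm, ":cn:", .char_ngrams(lw, 1L, 4L)))
    }
  }

  if (on("neighbor") && has_parse) {
    adj <- vector("list", n)
    for (r in seq_len(nrow(sent$deps))) {
      h <- sent$deps$head[r]; d <- sent$deps$dep[r]; lab <- sent$deps$label[r]
      if (h >= 1L && h <= n) {
        adj[[h]] <- rbind(adj[[h]], data.frame(to = d, label = lab))
        adj[[d]] <- rbind(adj[[d]], data.frame(to = h, label = lab))
      }
    }
    for (i in heads) {
      if (is.na(i) || is.null(adj[[i]])) next
      for (r1 in seq_len(nrow(adj[[i]]))) {
        t1 <- adj[[i]]$to[r1]; l1 <- adj[[i]]$label[r1]
        feats <- c(feats, paste0("nbr:td2:", blind[i], "_", l1, "_", blind[t1]),
                   paste0("nbr:d2:", l1))
        if (!is.null(adj[[t1]])) {
          for (r2 in seq_len(nrow(adj[[t1]]))) {
            t2 <- adj[[t1]]$to[r2]; l2 <- adj[[t1]]$label[r2]
            if (t2 == i) next
            feats <- c(feats,
                       paste0("nbr:td3:", blind[i], "_", l1, "_", blind[t1],
                              "_", l2, "_", blind[t2]),
                       paste0("nbr:t2:", blind[t1], "_", blind[t2]),
                       paste0("nbr:d22:", l1, "_", l2))
          }
        }
      }
    }
  }

  if (on("window")) {
    for (nm in names(heads)) {
      i <- heads[[nm]]
      if (is.na(i)) next
      win <- blind[max(1L, i - 3L):min(n, i + 3L)]
      feats <- c(feats, paste0("win:", nm, ":", .ngrams(win, 1L, 4L)))
    }
  }

  if (on("pair")) {
    idx_c <- tokens_in_span(sent, m$start[chem], m$end[chem])
    idx_d <- tokens_in_span(sent, m$start[dis], m$end[dis])
    span <- range(c(idx_c, idx_d, heads[!is.na(heads)]))
    lo <- max(1L, span[1] - 3L); hi <- min(n, span[2] + 3L)
    win <- blind[lo:hi]
    feats <- c(feats, paste0("pair:w:", .ngrams(win, 1L, 4L)))
    if (has_parse) {
      lab_of <- rep("root", n)
      lab_of[sent$deps$dep] <- sent$deps$label
      labs <- lab_of[lo:hi]
      feats <- c(feats, paste0("pair:d:", .ngrams(labs, 2L, 2L)),
                 paste0("pair:t:", .ngrams(win, 2L, 3L)))
      mixed <- as.vector(rbind(win, labs))
      feats <- c(feats, paste0("pair:m:", .ngrams(mixed, 2L, 4L)))
    }
  }

  if (on("path") && has_parse && !is.na(heads[1]) && !is.na(heads[2])) {
    sp <- shortest_dependency_path(sent, heads[[1]], heads[[2]])
    if (!is.null(sp)) {
      plen <- nrow(sp$arcs)
      bucket <- if (plen <= 4L) as.character(plen) else "5+"
      feats <- c(feats, paste0("sdp:len:", bucket))
      pw <- blind[sp$nodes]
      pl <- sp$arcs$label
      feats <- c(feats, paste0("sdp:w:", .ngrams(pw, 1L, 4L)),
                 paste0("sdp:d:", .ngrams(pl, 1L, 4L)))
      if (plen >= 1L) {
        for (e in seq_len(plen)) {
          gov_dep <- if (sp$arcs$dir[e] == "down") {
            c(pw[e], pw[e + 1L])
          } else {
            c(pw[e + 1L], pw[e])
          }
          feats <- c(feats, paste0("sdp:gd:", paste(gov_dep, collapse = "_")),
                     paste0("sdp:gd1:", gov_dep),
                     # edge walk and its sub-structures
                     paste0("sdp:ew:", pw[e], "_", pl[e], "_", pw[e + 1L]),
                     paste0("sdp:ew-sub:", pw[e], "_", pl[e]),
                     paste0("sdp:ew-sub:", pl[e], "_", pw[e + 1L]))
        }
        if (plen >= 2L) {
          for (v in seq_len(plen - 1L)) {
            feats <- c(feats,
                       paste0("sdp:vw:", pl[v], "_", pw[v + 1L], "_", pl[v + 1L]),
                       paste0("sdp:vw-sub:", pl[v], "_", pw[v + 1L]),
                       paste0("sdp:vw-sub:", pw[v + 1L], "_", pl[v + 1L]))
          }
        }
      }
    }
  }

  if (!length(feats)) return(stats::setNames(numeric(), character()))
  tab <- table(feats)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Train the linear relation classifier
#'
#' Fits an L2-regularized hinge-loss (linear support vector) classifier on
#' sparse feature-count vectors; the fitted hyperplane is extracted into a
#' named sparse weight vector so scoring is a dot product.
#'
#' @param features list of named numeric vectors (one per instance).
#' @param labels character/factor with levels `CID` and `none`.
#' @param C regularization constant.
#' @param seed integer seed (kept for interface stability; the fit itself is
#'   deterministic).
#' @return object of class `relation_model` with `weights`, `bias` and
#'   `feature_names`.
#' @export
train_relation_model <- function(features, labels, C = 1, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(length(features) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("training data has a single class: missing ",
         setdiff(c("CID", "none"), unique(labels)))
  }
  dict <- sort(unique(unlist(lapply(features, names), use.names = FALSE)))
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (r in seq_along(features)) {
    f <- features[[r]]
    if (!length(f)) next
    j <- match(names(f), dict)
    ii <- c(ii, rep(r, length(f))); jj <- c(jj, j); xx <- c(xx, unname(f))
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(features), length(dict)))
  y <- factor(labels, levels = c("CID", "none"))
  cw <- length(y) / (2 * table(y))
  set.seed(seed)
  fit <- e1071::svm(X, y, kernel = "linear", cost = C, scale = FALSE,
                    class.weights = cw)
  w <- as.numeric(Matrix::t(fit$coefs) %*% SparseM::as.matrix(fit$SV))
  b <- -fit$rho
  # libsvm's positive decision side is the first class named in the
  # decision-value column; flip so positive score always means CID
  pos <- strsplit(colnames(fit$decision.values), "/", fixed = TRUE)[[1]][1]
  if (pos != "CID") { w <- -w; b <- -b }
  keep <- w != 0
  structure(list(weights = stats::setNames(w[keep], dict[keep]), bias = b,
                 feature_names = dict, C = C),
            class = "relation_model")
}

#' @export
print.relation_model <- function(x, ...) {
  cat(sprintf("<relation_model: %d nonzero weights over %d features, C = %g>\n",
              length(x$weights), length(x$feature_names), x$C))
  invisible(x)
}

#' Decision score of a feature vector
#' @param model a `relation_model`.
#' @param feats named numeric feature-count vector.
#' @return numeric score; positive means CID.
#' @export
relation_score <- function(model, feats) {
  common <- intersect(names(feats), names(model$weights))
  sum(model$weights[common] * feats[common]) + model$bias
}

#' Abstract-level CID prediction for one document
#'
#' Classifies every intra-sentence candidate pair and returns the set of
#' distinct (chemical id, disease id) pairs with at least one positive
#' candidate. Unlinked mentions are excluded. With `use_coref = TRUE` the
#' sieve cascade and label propagation are applied first, which adds
#' candidates for inter-sentence relations.
#'
#' @param doc a `cid_document` with normalized mentions.
#' @param model a `relation_model`.
#' @param ontology a `cid_ontology` (needed when `use_coref = TRUE`).
#' @param use_coref apply coreference propagation before candidate
#'   generation.
#' @param feature_config passed to [extract_relation_features()].
#' @param hypo hyponym dictionaries for sieve 9.
#' @return data.frame with columns `chemical_id`, `disease_id`.
#' @export
predict_cid <- function(doc, model, ontology = NULL, use_coref = FALSE,
                        feature_config = NULL, hypo = hyponym_dictionaries()) {
  if (use_coref) {
    stopifnot(!is.null(ontology))
    doc <- propagate_entity_labels(doc, run_sieves(doc, ontology, hypo = hypo))
  }
  cands <- candidate_pairs(doc)
  out <- empty_relations()
  m <- doc$mentions
  for (r in seq_len(nrow(cands))) {
    cid <- m$concept_id[cands$chem[r]]; did <- m$concept_id[cands$dis[r]]
    if (!.linked(cid) || !.linked(did)) next
    f <- extract_relation_features(doc, cands$chem[r], cands$dis[r],
                                   feature_config)
    if (relation_score(model, f) > 0) {
      out <- rbind(out, data.frame(chemical_id = cid, disease_id = did,
                                   stringsAsFactors = FALSE))
    }
  }
  unique(out)
}
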