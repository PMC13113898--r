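# Building blocks of the YOLO11 nano baseline: bottlenecks, C3k/C3k2 stages,
# SPPF, the position-sensitive attention stage (C2PSA) and the decoupled
# detection head. Widths follow the published nano scaling (width 0.25, depth
# 0.5, max channels 1024).

m_bottleneck <- function(c1, c2, shortcut = TRUE, k = c(3L, 3L), e = 0.5) {
  ch <- max(as.integer(round(c2 * e)), 1L)
  new_module("m_bneck", add = shortcut && c1 == c2,
             cv1 = m_conv(c1, ch, k[1]),
             cv2 = m_conv(ch, c2, k[2]))
}

fwd.m_bneck <- function(m, x, train = FALSE) {
  y <- fwd(m$cv2, fwd(m$cv1, x, train), train)
  if (m$add) op_add(y, x) else y
}

mod_profile.m_bneck <- function(m, inshape) {
  p1 <- mod_profile(m$cv1, inshape)
  p2 <- mod_profile(m$cv2, p1$out)
  elt <- if (m$add) prod(p2$out) else 0
  prof(p2$out, p1$flops + p2$flops + elt, p1$params + p2$params)
}
mod_params.m_bneck <- function(m) collect_params(list(cv1 = m$cv1, cv2 = m$cv2))
mod_fuse.m_bneck <- function(m) { fuse_children(list(m$cv1, m$cv2)); invisible(m) }

m_c3k <- function(c1, c2, n = 2L, shortcut = TRUE, e = 0.5, k = 3L) {
  ch <- as.integer(round(c2 * e))
  new_module("m_c3k",
             cv1 = m_conv(c1, ch, 1), cv2 = m_conv(c1, ch, 1),
             cv3 = m_conv(2L * ch, c2, 1),
             blocks = lapply(seq_len(n), function(i)
               m_bottleneck(ch, ch, shortcut, k = c(k, k), e = 1.0)),
             ch = ch)
}

fwd.m_c3k <- function(m, x, train = FALSE) {
  a <- fwd(m$cv1, x, train)
  for (b in m$blocks) a <- fwd(b, a, train)
  fwd(m$cv3, op_cat(list(a, fwd(m$cv2, x, train)), 1L), train)
}

mod_profile.m_c3k <- function(m, inshape) {
  p1 <- mod_profile(m$cv1, inshape); p2 <- mod_profile(m$cv2, inshape)
  fl <- p1$flops + p2$flops; np <- p1$params + p2$params
  s <- p1$out
  for (b in m$blocks) { pb <- mod_profile(b, s); s <- pb$out; fl <- fl + pb$flops; np <- np + pb$params }
  p3 <- mod_profile(m$cv3, c(2L * m$ch, inshape[2], inshape[3]))
  prof(p3$out, fl + p3$flops, np + p3$params, concats = 1)
}
mod_params.m_c3k <- function(m)
  collect_params(c(list(cv1 = m$cv1, cv2 = m$cv2, cv3 = m$cv3),
                   stats::setNames(m$blocks, sprintf("b%d", seq_along(m$blocks)))))
mod_fuse.m_c3k <- function(m) { fuse_children(c(list(m$cv1, m$cv2, m$cv3), m$blocks)); invisible(m) }

m_c3k2 <- function(c1, c2, n = 1L, c3k = FALSE, e = 0.5) {
  ch <- as.integer(round(c2 * e))
  blocks <- lapply(seq_len(n), function(i)
    if (c3k) m_c3k(ch, ch, n = 2L) else m_bottleneck(ch, ch, TRUE, e = 0.5))
  new_module("m_c3k2", ch = ch, n = as.integer(n),
             cv1 = m_conv(c1, 2L * ch, 1),
             cv2 = m_conv((2L + n) * ch, c2, 1),
             blocks = blocks)
}

fwd.m_c3k2 <- function(m, x, train = FALSE) {
  y <- fwd(m$cv1, x, train)
  parts <- list(op_narrow(y, 1L, 1L, m$ch), op_narrow(y, 1L, m$ch + 1L, m$ch))
  for (b in m$blocks)
    parts[[length(parts) + 1L]] <- fwd(b, parts[[length(parts)]], train)
  fwd(m$cv2, op_cat(parts, 1L), train)
}

mod_profile.m_c3k2 <- function(m, inshape) {
  p1 <- mod_profile(m$cv1, inshape)
  H <- p1$out[2]; W <- p1$out[3]
  fl <- p1$flops; np <- p1$params; cc <- 1
  for (b in m$blocks) {
    pb <- mod_profile(b, c(m$ch, H, W))
    fl <- fl + pb$flops; np <- np + pb$params; cc <- cc + pb$concats
  }
  p2 <- mod_profile(m$cv2, c((2L + m$n) * m$ch, H, W))
  prof(p2$out, fl + p2$flops, np + p2$params, cc)
}
mod_params.m_c3k2 <- mod_params.m_tasm
mod_fuse.m_c3k2 <- function(m) { fuse_children(c(list(m$cv1, m$cv2), m$blocks)); invisible(m) }

m_sppf <- function(c1, c2, k = 5L) {
  ch <- c1 %/% 2L
  new_module("m_sppf", k = as.integer(k), ch = ch,
             cv1 = m_conv(c1, ch, 1), cv2 = m_conv(4L * ch, c2, 1))
}

fwd.m_sppf <- function(m, x, train = FALSE) {
  a <- fwd(m$cv1, x, train)
  p1 <- op_maxpool(a, m$k, 1L, m$k %/% 2L)
  p2 <- op_maxpool(p1, m$k, 1L, m$k %/% 2L)
  p3 <- op_maxpool(p2, m$k, 1L, m$k %/% 2L)
  fwd(m$cv2, op_cat(list(a, p1, p2, p3), 1L), train)
}

mod_profile.m_sppf <- function(m, inshape) {
  p1 <- mod_profile(m$cv1, inshape)
  p2 <- mod_profile(m$cv2, c(4L * m$ch, p1$out[2], p1$out[3]))
  prof(p2$out, p1$flops + p2$flops, p1$params + p2$params, concats = 1)
}
mod_params.m_sppf <- function(m) collect_params(list(cv1 = m$cv1, cv2 = m$cv2))
mod_fuse.m_sppf <- function(m) { fuse_children(list(m$cv1, m$cv2)); invisible(m) }

# -- position-sensitive attention stage --------------------------------------

m_attn <- function(dim, num_heads, attn_ratio = 0.5) {
  head_dim <- dim %/% num_heads
  key_dim <- as.integer(head_dim * attn_ratio)
  nh_kd <- key_dim * num_heads
  h <- dim + nh_kd * 2L
  new_module("m_attn", dim = dim, num_heads = num_heads, key_dim = key_dim,
             head_dim = head_dim, scale = key_dim^-0.5,
             qkv = m_conv(dim, h, 1, act = "identity"),
             proj = m_conv(dim, dim, 1, act = "identity"),
             pe = m_conv(dim, dim, 3, g = dim, act = "identity"))
}

fwd.m_attn <- function(m, x, train = FALSE) {
  d <- dim(x$value); H <- d[2]; W <- d[3]; N <- H * W
  qkv <- fwd(m$qkv, x, train)
  per_head <- 2L * m$key_dim + m$head_dim
  outs <- vector("list", m$num_heads)
  vs <- vector("list", m$num_heads)
  for (hh in seq_len(m$num_heads)) {
    base <- (hh - 1L) * per_head
    q <- op_reshape(op_narrow(qkv, 1L, base + 1L, m$key_dim), c(m$key_dim, N))
    k <- op_reshape(op_narrow(qkv, 1L, base + m$key_dim + 1L, m$key_dim), c(m$key_dim, N))
    v <- op_reshape(op_narrow(qkv, 1L, base + 2L * m$key_dim + 1L, m$head_dim), c(m$head_dim, N))
    attn <- op_softmax(op_scale(op_matmul(op_tmat(q), k), m$scale), margin = 2)
    outs[[hh]] <- op_reshape(op_matmul(v, op_tmat(attn)), c(m$head_dim, H, W))
    vs[[hh]] <- op_reshape(v, c(m$head_dim, H, W))
  }
  o <- op_cat(outs, 1L)
  vmap <- op_cat(vs, 1L)
  fwd(m$proj, op_add(o, fwd(m$pe, vmap, train)), train)
}

mod_profile.m_attn <- function(m, inshape) {
  N <- inshape[2] * inshape[3]
  pq <- mod_profile(m$qkv, inshape)
  pp <- mod_profile(m$proj, inshape)
  pe <- mod_profile(m$pe, inshape)
  # activation-activation matrix products carry no weights and are outside
  # the frozen FLOP convention (parameterized layers + fusion elementwise ops)
  prof(inshape, pq$flops + pp$flops + pe$flops + prod(inshape),
       pq$params + pp$params + pe$params)
}
mod_params.m_attn <- function(m) collect_params(list(qkv = m$qkv, proj = m$proj, pe = m$pe))
mod_fuse.m_attn <- function(m) { fuse_children(list(m$qkv, m$proj, m$pe)); invisible(m) }

m_psablock <- function(c, num_heads) {
  new_module("m_psablock",
             attn = m_attn(c, num_heads),
             ffn1 = m_conv(c, 2L * c, 1),
             ffn2 = m_conv(2L * c, c, 1, act = "identity"))
}

fwd.m_psablock <- function(m, x, train = FALSE) {
  x <- op_add(x, fwd(m$attn, x, train))
  op_add(x, fwd(m$ffn2, fwd(m$ffn1, x, train), train))
}

mod_profile.m_psablock <- function(m, inshape) {
  pa <- mod_profile(m$attn, inshape)
  p1 <- mod_profile(m$ffn1, inshape)
  p2 <- mod_profile(m$ffn2, p1$out)
  prof(inshape, pa$flops + p1$flops + p2$flops + 2 * prod(inshape),
       pa$params + p1$params + p2$params)
}
mod_params.m_psablock <- function(m)
  collect_params(list(attn = m$attn, ffn1 = m$ffn1, ffn2 = m$ffn2))
mod_fuse.m_psablock <- function(m) { fuse_children(list(m$attn, m$ffn1, m$ffn2)); invisible(m) }

m_c2psa <- function(c1, n = 1L, e = 0.5) {
  ch <- as.integer(c1 * e)
  new_module("m_c2psa", ch = ch,
             cv1 = m_conv(c1, 2L * ch, 1),
             cv2 = m_conv(2L * ch, c1, 1),
             blocks = lapply(seq_len(n), function(i)
               m_psablock(ch, num_heads = max(1L, ch %/% 64L))))
}

fwd.m_c2psa <- function(m, x, train = FALSE) {
  y <- fwd(m$cv1, x, train)
  a <- op_narrow(y, 1L, 1L, m$ch)
  b <- op_narrow(y, 1L, m$ch + 1L, m$ch)
  for (blk in m$blocks) b <- fwd(blk, b, train)
  fwd(m$cv2, op_cat(list(a, b), 1L), train)
}

mod_profile.m_c2psa <- function(m, inshape) {
  p1 <- mod_profile(m$cv1, inshape)
  fl <- p1$flops; np <- p1$params
  s <- c(m$ch, inshape[2], inshape[3])
  for (blk in m$blocks) { pb <- mod_profile(blk, s); fl <- fl + pb$flops; np <- np + pb$params }
  p2 <- mod_profile(m$cv2, c(2L * m$ch, inshape[2], inshape[3]))
  prof(p2$out, fl + p2$flops, np + p2$params, concats = 1)
}
mod_params.m_c2psa <- mod_params.m_tasm
mod_fuse.m_c2psa <- function(m) { fuse_children(c(list(m$cv1, m$cv2), m$blocks)); invisible(m) }

# -- decoupled detection head (baseline) -------------------------------------

m_detect_v11 <- function(nc, channels, reg_max = 16L) {
  c2 <- max(16L, channels[1] %/% 4L, reg_max * 4L)
  c3 <- max(channels[1], min(nc, 100L))
  mk_reg <- function(x) m_seq(list(
    m_conv(x, c2, 3), m_conv(c2, c2, 3),
    m_conv(c2, 4L * reg_max, 1, act = "identity", bn = FALSE, bias = TRUE)))
  mk_cls <- function(x) m_seq(list(
    m_conv(x, x, 3, g = x), m_conv(x, c3, 1),
    m_conv(c3, c3, 3, g = c3), m_conv(c3, c3, 1),
    m_conv(c3, nc, 1, act = "identity", bn = FALSE, bias = TRUE)))
  regs <- lapply(channels, mk_reg)
  clss <- lapply(channels, mk_cls)
  for (i in seq_along(channels))
    init_head_biases(clss[[i]]$mods[[length(clss[[i]]$mods)]],
                     regs[[i]]$mods[[length(regs[[i]]$mods)]], nc, c(8, 16, 32)[i])
  new_module("m_detect", nc = nc, reg_max = reg_max, channels = channels,
             reg = regs, cls = clss)
}

fwd.m_detect <- function(m, x, train = FALSE) {
  lapply(seq_along(x), function(i) list(
    cls = fwd(m$cls[[i]], x[[i]], train),
    reg = fwd(m$reg[[i]], x[[i]], train)))
}

mod_profile.m_detect <- function(m, inshape) {
  # inshape: list of level shapes
  fl <- 0; np <- 0
  outs <- vector("list", length(inshape))
  for (i in seq_along(inshape)) {
    pr <- mod_profile(m$reg[[i]], inshape[[i]])
    pc <- mod_profile(m$cls[[i]], inshape[[i]])
    fl <- fl + pr$flops + pc$flops; np <- np + pr$params + pc$params
    outs[[i]] <- list(cls = pc$out, reg = pr$out)
  }
  prof(outs, fl, np)
}
mod_params.m_detect <- function(m) {
  ch <- c(stats::setNames(m$reg, sprintf("reg%d", seq_along(m$reg))),
          stats::setNames(m$cls, sprintf("cls%d", seq_along(m$cls))))
  collect_params(ch)
}
mod_fuse.m_detect <- function(m) { fuse_children(c(m$reg, m$cls)); invisible(m) }
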