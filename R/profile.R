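# Analytic complexity profile.
#
# Parameters are counted by exhaustive traversal of the trainable tensors of
# an instantiated model and attributed to components by ownership. Multiply-
# accumulate counts are computed analytically per layer at the configured
# input size; one MAC is reported as one FLOP (the convention under which
# lightweight segmentation models report "GFLOPs"). Normalisation layers,
# activations, pooling and the wavelet transforms contribute no MACs.

conv_macs <- function(k, cin, cout, ho, wo) k * k * cin * cout * ho * wo

cnn_block_macs <- function(C, H, W) {
  (49 * C + C * C) * H * W                    # 7x7 depthwise + 1x1 pointwise
}

msq_block_macs <- function(C, heads, H, W, single_scale = FALSE) {
  N <- H * W
  ck <- C / 2
  strides <- if (single_scale) msq_strides[1] else msq_strides
  np <- length(strides)
  total <- C * (np * ck) * N +                # query projection
    (np * ck) * C * N                         # output projection
  for (s in strides) {
    Mi <- N / s^2
    total <- total +
      C * C * N +                             # kernel = stride compression
      C * (2 * ck) * Mi +                     # key/value projection
      9 * ck * Mi +                           # 3x3 depthwise value enhancement
      2 * N * Mi * ck                         # Q K^T and SA V over h/2 heads
  }
  total
}

warm_macs <- function(C, f_int, H, W) {
  4 * (2 * C * f_int + f_int) * (H / 2) * (W / 2)
}

#' Profile parameters and multiply-accumulate operations per component
#'
#' @param cfg a [model_config()]; ignored if `model` is given.
#' @param input_size evaluation size (square). Defaults to the configuration's
#'   `input_size`.
#' @param model optionally, an already-built `seg_network` to profile.
#' @return a `dermseg_profile` list with per-component parameter and MAC
#'   counts (raw, millions / billions and percentages) and the totals.
#' @export
profile_network <- function(cfg = model_config(), input_size = NULL,
                            model = NULL) {
  if (!is.null(model)) cfg <- model$meta$cfg else model <- build_model(cfg)
  if (is.null(input_size)) input_size <- cfg$input_size
  S <- cfg$num_stages
  chs <- cfg$stage_channels
  ch <- model$children

  comp_names <- c("encoder_cnn", "encoder_msq", "encoder_other",
                  "decoder_cnn", "decoder_msq", "decoder_other", "warm")
  params <- stats::setNames(numeric(7), comp_names)
  macs <- stats::setNames(numeric(7), comp_names)

  # stage resolutions after the stem
  H1 <- input_size / cfg$stem_stride
  res <- H1 / 2^(seq_len(S) - 1)

  params["encoder_other"] <- count_params(ch$stem_conv) + count_params(ch$stem_bn)
  macs["encoder_other"] <- conv_macs(3, cfg$in_channels, chs[1], H1, H1)

  stage_counts <- function(stage, i, enc) {
    pcnn <- pmsq <- mcnn <- mmsq <- 0
    for (nm in names(stage$children)) {
      b <- stage$children[[nm]]
      if (inherits(b, "cnn_block")) {
        pcnn <- pcnn + count_params(b)
        mcnn <- mcnn + cnn_block_macs(chs[i], res[i], res[i])
      } else if (inherits(b, "msq_block")) {
        pmsq <- pmsq + count_params(b)
        mmsq <- mmsq + msq_block_macs(chs[i], cfg$heads[i], res[i], res[i],
                                      cfg$msq_single_scale)
      }
    }
    c(pcnn, pmsq, mcnn, mmsq)
  }

  for (i in seq_len(S)) {
    sc <- stage_counts(ch[[paste0("enc", i)]], i, TRUE)
    params["encoder_cnn"] <- params["encoder_cnn"] + sc[1]
    params["encoder_msq"] <- params["encoder_msq"] + sc[2]
    macs["encoder_cnn"] <- macs["encoder_cnn"] + sc[3]
    macs["encoder_msq"] <- macs["encoder_msq"] + sc[4]
    if (i < S) {
      params["encoder_other"] <- params["encoder_other"] +
        count_params(ch[[paste0("down", i)]])
      macs["encoder_other"] <- macs["encoder_other"] +
        conv_macs(2, chs[i], chs[i + 1], res[i + 1], res[i + 1])
    }
  }
  for (i in seq_len(S - 1L)) {
    sc <- stage_counts(ch[[paste0("dec", i)]], i, FALSE)
    params["decoder_cnn"] <- params["decoder_cnn"] + sc[1]
    params["decoder_msq"] <- params["decoder_msq"] + sc[2]
    macs["decoder_cnn"] <- macs["decoder_cnn"] + sc[3]
    macs["decoder_msq"] <- macs["decoder_msq"] + sc[4]
    params["decoder_other"] <- params["decoder_other"] +
      count_params(ch[[paste0("up", i)]])
    # 2x2 transposed conv: 4 * Cin * Cout at the coarse resolution
    macs["decoder_other"] <- macs["decoder_other"] +
      chs[i + 1] * chs[i] * res[i] * res[i]
  }
  if (cfg$use_warm) {
    params["warm"] <- count_params(ch$warm)
    macs["warm"] <- warm_macs(chs[1], cfg$gate_width, res[1], res[1])
  }
  head_res <- input_size
  if (cfg$stem_stride == 2L) {
    params["decoder_other"] <- params["decoder_other"] +
      count_params(ch$final_up) + count_params(ch$final_bn)
    macs["decoder_other"] <- macs["decoder_other"] +
      4 * chs[1] * chs[1] * H1 * H1
  }
  params["decoder_other"] <- params["decoder_other"] + count_params(ch$head)
  macs["decoder_other"] <- macs["decoder_other"] +
    chs[1] * cfg$out_channels * head_res * head_res

  total_p <- sum(params)
  total_m <- sum(macs)
  stopifnot(total_p == count_params(model))

  groups <- list(
    encoder = c("encoder_cnn", "encoder_msq", "encoder_other"),
    decoder = c("decoder_cnn", "decoder_msq", "decoder_other"),
    warm = "warm")
  summarise <- function(v) {
    g <- vapply(groups, function(nms) sum(v[nms]), 0)
    c(g, total = sum(v))
  }
  structure(list(
    input_size = input_size,
    components = list(params = params, macs = macs),
    params = summarise(params),
    macs = summarise(macs),
    params_M = summarise(params) / 1e6,
    macs_G = summarise(macs) / 1e9,
    param_pct = 100 * summarise(params) / total_p,
    mac_pct = 100 * summarise(macs) / total_m,
    flop_convention = "1 multiply-accumulate = 1 FLOP"),
    class = "dermseg_profile")
}

#' @export
print.dermseg_profile <- function(x, ...) {
  p <- x$components$params
  m <- x$components$macs
  tp <- sum(p); tm <- sum(m)
  row <- function(label, pp, mm) {
    cat(sprintf("%-16s %8.2f %9.2f %8.2f %9.2f\n", label, pp / 1e6,
                100 * pp / tp, mm / 1e9, 100 * mm / tm))
  }
  cat(sprintf("Component profile at input %dx%d (%s)\n",
              x$input_size, x$input_size, x$flop_convention))
  cat(sprintf("%-16s %8s %9s %8s %9s\n", "Stage", "Params(M)", "Param(%)",
              "MACs(G)", "MAC(%)"))
  row("Encoder", sum(p[1:3]), sum(m[1:3]))
  row("  CNN", p["encoder_cnn"], m["encoder_cnn"])
  row("  MSQFormer", p["encoder_msq"], m["encoder_msq"])
  row("  other", p["encoder_other"], m["encoder_other"])
  row("Decoder", sum(p[4:6]), sum(m[4:6]))
  row("  CNN", p["decoder_cnn"], m["decoder_cnn"])
  row("  MSQFormer", p["decoder_msq"], m["decoder_msq"])
  row("  other", p["decoder_other"], m["decoder_other"])
  row("WARM", p["warm"], m["warm"])
  row("Complete model", tp, tm)
  invisible(x)
}

#' Serialise a profile report to a plain list (for JSON export)
#' @param x a `dermseg_profile`.
#' @return nested list of numbers.
#' @export
profile_as_list <- function(x) {
  list(input_size = x$input_size,
       flop_convention = x$flop_convention,
       params = as.list(x$params),
       params_M = as.list(x$params_M),
       param_pct = as.list(x$param_pct),
       macs = as.list(x$macs),
       macs_G = as.list(x$macs_G),
       mac_pct = as.list(x$mac_pct),
       components_params = as.list(x$components$params),
       components_macs = as.list(x$components$macs))
}
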