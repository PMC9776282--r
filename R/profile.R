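# Analytic parameter and FLOP profiler.
#
# Parameter counts are exact (every trainable scalar). FLOPs use the
# multiply-accumulate convention (1 MAC = 1 FLOP) over convolution and linear
# layers, the quantities module-walking profilers report; the attention
# matrix products can be added with `include_attention = TRUE`.
# Normalizations, activations, poolings and bias additions are not counted.

#' Profile a model's parameters and forward FLOPs
#'
#' @param model a `pcvt_model`, or a [model_config()] (profiled with the
#'   model's default `"valc"` head unless `head` is given).
#' @param input_size input side in pixels; defaults to the configured size.
#' @param include_attention also count the Q K^T and A V matrix products of
#'   every attention layer.
#' @param head head to profile when `model` is a bare config.
#' @return Object of class `pcvt_profile`: list with `params` (exact count),
#'   `params_m` (millions, 2 decimals), `macs`, `gflops` (2 decimals),
#'   `gflops_raw` and a per-layer `layers` data frame.
#' @export
profile_model <- function(model, input_size = NULL, include_attention = FALSE,
                          head = c("valc", "light")) {
  if (inherits(model, "pcvt_model")) {
    cfg <- model$config
    head <- model$head
  } else {
    cfg <- model
    validate_model_config(cfg)
    head <- match.arg(head)
  }
  if (is.null(input_size)) input_size <- cfg$input_size
  rows <- list()
  add <- function(module, layer, params, macs)
    rows[[length(rows) + 1]] <<- data.frame(module = module, layer = layer,
                                            params = params, macs = macs)

  side <- input_size %/% 2                       # stem conv, stride 2
  st_ch <- cfg$stem_channels
  add("cpe", "conv3x3/2", st_ch * cfg$in_channels * 9 + st_ch,
      side^2 * st_ch * cfg$in_channels * 9)
  side <- (side + 2 - 3) %/% 2 + 1               # max pooling
  for (i in seq_len(cfg$r)) {
    side <- side %/% 2
    add("cpe", sprintf("block_scaling%d.conv2x2/2", i),
        st_ch * st_ch * 4 + st_ch, side^2 * st_ch * st_ch * 4)
    add("cpe", sprintf("block_scaling%d.conv1x1", i),
        st_ch * st_ch + st_ch, side^2 * st_ch * st_ch)
  }

  entry <- stage_entry_channels(cfg)
  for (s in seq_along(cfg$stages)) {
    st <- cfg$stages[[s]]
    ch <- entry[s]
    tokens <- side^2
    for (b in seq_len(st$l)) {
      lab <- sprintf("ptf%d.block%d", s, b)
      add(lab, "qkv_dwconv3x3", 3 * (ch * 9 + ch), 3 * tokens * ch * 9)
      add(lab, "attention", 0,
          if (include_attention) 2 * tokens^2 * ch else 0)
      add(lab, "layernorm1", 2 * ch, 0)
      add(lab, "ff_conv1x1_down", ch * (ch %/% 2) + ch %/% 2,
          tokens * (ch %/% 2) * ch)
      add(lab, "ff_conv1x1_up", (ch %/% 2) * ch + ch,
          tokens * ch * (ch %/% 2))
      add(lab, "layernorm2", 2 * ch, 0)
    }
    add(sprintf("ptf%d", s), "bcp_conv3x3", st$d0 * ch * 9 + st$d0,
        tokens * st$d0 * ch * 9)
    add(sprintf("ptf%d", s), "bcp_batchnorm", 2 * st$d0, 0)
    side <- side %/% 2
  }

  final_d0 <- cfg$stages[[length(cfg$stages)]]$d0
  feat <- side^2
  if (head == "valc") {
    f <- cfg$pixel_shuffle_factor
    cin <- final_d0 %/% (f * f)
    cc <- cfg$condense_channels
    add("valc", "condense_conv", cc * cin * f * f + cc,
        feat * cc * cin * f * f)
    add("valc", "w_AD", 1, 0)
    add("valc", "fc", cfg$d_class * feat + cfg$d_class, cfg$d_class * feat)
  } else {
    hid <- cfg$head_hidden
    add("head", "fc1", hid * final_d0 * feat + hid, hid * final_d0 * feat)
    add("head", "fc2", cfg$d_class * hid + cfg$d_class, cfg$d_class * hid)
  }

  layers <- do.call(rbind, rows)
  params <- sum(layers$params)
  macs <- sum(layers$macs)
  structure(list(params = params, params_m = round(params / 1e6, 2),
                 macs = macs, gflops = round(macs / 1e9, 2),
                 gflops_raw = macs / 1e9, layers = layers,
                 input_size = input_size, head = head,
                 include_attention = include_attention),
            class = "pcvt_profile")
}

#' @export
print.pcvt_profile <- function(x, ...) {
  cat(sprintf("parameters: %.2f M (%d)\n", x$params / 1e6, x$params))
  cat(sprintf("forward:    %.2f GFLOPs at %d x %d (MAC-counted%s)\n",
              x$gflops_raw, x$input_size, x$input_size,
              if (x$include_attention) ", attention included" else ""))
  invisible(x)
}
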