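#!/usr/bin/env Rscript
# Constraint search that fixed the default DHuNeT schedule.
#
# The published hyperparameter table states the trainable-parameter count
# (1,081,942) but not the schedule (depth, filters, normalization,
# upsampling). This script enumerates standard dual-UNet schedules --
# depth 2-5, base filters 4-32, batchnorm on/off, upsampling transposed /
# nearest+conv -- counts each candidate's trainable parameters in closed
# form, verifies the closed form against an instantiated model, and freezes
# the configuration whose count is closest to the target (exact if one
# exists) into inst/extdata/dhunet-default.yaml.
#
# Counting conventions (mirrored by the package builder):
#   * two 3x3 convolutions per block; bottleneck doubles the deepest width
#   * a convolution followed by batchnorm carries no bias (the mean
#     subtraction would cancel it); batchnorm adds scale+shift per channel
#   * transposed upsampling: 2x2 stride-2 kernel; interp upsampling:
#     parameter-free nearest-neighbour followed by a 3x3 convolution
#   * each UNet ends in a biased 1x1 sigmoid head; UNet-2 takes 4 input
#     channels (image + UNet-1 mask)
suppressMessages(library(dhunet))

target <- 1081942L

conv_p <- function(cin, cout, k, bn) k * k * cin * cout + (if (bn) 2 * cout else cout)

unet_count <- function(cin, base, depth, bn, up) {
  f <- base * 2^(0:depth)
  tot <- 0
  cprev <- cin
  for (i in 1:depth) {
    tot <- tot + conv_p(cprev, f[i], 3, bn) + conv_p(f[i], f[i], 3, bn)
    cprev <- f[i]
  }
  fb <- f[depth + 1]
  tot <- tot + conv_p(cprev, fb, 3, bn) + conv_p(fb, fb, 3, bn)
  cup <- fb
  for (i in depth:1) {
    tot <- tot + (if (up == "transposed") 4 * cup * f[i] + (if (bn) 2 * f[i] else f[i])
                  else conv_p(cup, f[i], 3, bn))
    tot <- tot + conv_p(2 * f[i], f[i], 3, bn) + conv_p(f[i], f[i], 3, bn)
    cup <- f[i]
  }
  tot + (f[1] + 1)
}

grid <- expand.grid(depth = 2:5, base = 4:32, bn = c(FALSE, TRUE),
                    up = c("transposed", "interp"), stringsAsFactors = FALSE)
grid$count <- mapply(function(b, d, bn, up) {
  unet_count(3, b, d, bn, up) + unet_count(4, b, d, bn, up)
}, grid$base, grid$depth, grid$bn, grid$up)
grid$gap <- abs(grid$count - target)
grid <- grid[order(grid$gap, grid$count), ]

best <- grid[1, ]
cat(sprintf("target %d; best schedule: depth %d, base %d, batchnorm %s, %s => %d (gap %d)\n",
            target, best$depth, best$base, best$bn, best$up, best$count, best$gap))
if (best$gap > 0) {
  cat("no standard schedule matches the printed count exactly; freezing the nearest.\n")
}

cfg <- dhunet_config(depth = best$depth, base_filters = best$base,
                     use_batchnorm = best$bn, upsample_mode = best$up)
built <- count_parameters(build_dhunet(cfg, seed = 1))
stopifnot(built == best$count)  # closed form must agree with the builder
cat(sprintf("instantiated model confirms %d trainable parameters\n", built))

out <- file.path("inst", "extdata", "dhunet-default.yaml")
yaml::write_yaml(list(depth = best$depth, base_filters = best$base,
                      filter_growth = 2L, kernel_size = 3L,
                      use_batchnorm = best$bn, upsample_mode = best$up), out)
cat("frozen default written to", out, "\n")
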