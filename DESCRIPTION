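Package: fpmkit
Title: Fourier Ptychographic Microscopy Simulation, Reconstruction and Learning Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-angle LED-illuminated Fourier ptychographic
    microscopy (FPM) acquisition with an ideal coherent transfer function,
    reconstructs high-resolution complex amplitude by alternating-projection
    (Gerchberg-Saxton) phase retrieval, synthesizes the dual-channel
    (intensity, phase) network input from a low-resolution stack in a single
    Fourier-domain pass, builds seeded synthetic training datasets from
    procedural amplitude/phase sources, scores reconstructions with MSE, PSNR
    and global SSIM, and assembles a toy-scale multi-branch feature-fusion
    network with a pixel-recombination upsampling head and an Adam trainer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
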