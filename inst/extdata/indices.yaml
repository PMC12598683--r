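# Spectral reflectance index registry. `formula` is an R expression over
# band variables R<wavelength in nm>; `bands` lists the wavelengths the
# formula needs. Reflectance is on the fraction scale (0-1).
indices:
  - name: RGI
    label: Red/Green Index
    formula: R690 / R550
    bands: [690, 550]
  - name: PRI
    label: Photochemical Reflectance Index
    formula: (R531 - R570) / (R531 + R570)
    bands: [531, 570]
  - name: NDRE
    label: Normalized Difference Red Edge Index
    formula: (R790 - R720) / (R790 + R720)
    bands: [790, 720]
  - name: NDVI
    label: Normalized Difference Vegetation Index (red-edge form)
    formula: (R750 - R705) / (R750 + R705)
    bands: [750, 705]
  - name: NDVI_green
    label: Green Region Normalized Difference Vegetation Index
    formula: (R550 - R670) / (R550 + R670)
    bands: [550, 670]
  - name: ZMI
    label: Zarco-Tejada and Miller Index
    formula: R750 / R710
    bands: [750, 710]
  - name: GM1
    label: Gitelson and Merzlyak Index
    formula: R750 / R550
    bands: [750, 550]
  - name: FLAV_700_760
    label: Flavonoid proxy
    formula: (0.790 * R700) / (R760 + 0.40)
    bands: [700, 760]
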