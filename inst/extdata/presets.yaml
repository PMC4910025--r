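# Evolution parameter presets for typical targets.
# w: patch width (tangent), h: patch height (normal), r: sliding range,
# all in pixels; alpha/beta weigh similarity vs contrast.
cent2gr:  {w: 100, h: 200, r: 60, alpha: 0.5, beta: 0.5}
cent2mo:  {w: 100, h: 200, r: 60, alpha: 0.5, beta: 0.5}
mobmi:    {w: 100, h: 200, r: 10, alpha: 0.5, beta: 0.5}
outline:  {w: 50,  h: 25,  r: 10, alpha: 0.5, beta: 0.5}
mri_ct:   {w: 10,  h: 5,   r: 3,  alpha: 0.5, beta: 0.5}
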