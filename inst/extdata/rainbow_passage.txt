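When the sunlight strikes raindrops in the air, they act as a prism and form
a rainbow. The rainbow is a division of white light into many beautiful
colors. These take the shape of a long round arch, with its path high above,
and its two ends apparently beyond the horizon. There is, according to
legend, a boiling pot of gold at one end. People look, but no one ever finds
it. When a man looks for something beyond his reach, his friends say he is
looking for the pot of gold at the end of the rainbow.
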