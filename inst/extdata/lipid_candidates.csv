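name,formula,adduct,class,note
Tetradecanoylcarnitine AC(14:0),C21H41NO4,[M+H]+,acylcarnitine,mass matches the saturated species; source table prints the name under 14:1
Palmitoleoylcarnitine AC(16:1),C23H43NO4,[M+H]+,acylcarnitine,
Palmitoylcarnitine AC(16:0),C23H45NO4,[M+H]+,acylcarnitine,
Elaidic carnitine AC(18:1),C25H47NO4,[M+H]+,acylcarnitine,
lysoPC(16:0),C24H50NO7P,[M+Na]+,lysoPC,sodiated; lesion-core marker
lysoPC(18:1),C26H52NO7P,[M+Na]+,lysoPC,sodiated; lesion-core marker
lysoPC(18:0),C26H54NO7P,[M+Na]+,lysoPC,sodiated
Heme b,C34H32FeN4O4,[M]+.,heme,radical cation; hemorrhage marker
PC(16:0/20:4),C44H80NO8P,[M+K]+,PC,potassiated
PC(16:0/22:6),C46H80NO8P,[M+K]+,PC,potassiated; gray-matter marker
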