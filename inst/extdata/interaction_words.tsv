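activates	3
activate	3
activation	3
activator	3
stimulates	3
stimulate	3
enhances	3
enhance	3
induces	3
induce	3
upregulates	3
upregulate	3
up-regulates	3
potentiates	3
potentiate	3
increases	3
elevates	3
promotes	3
inhibits	4
inhibit	4
inhibition	4
inhibitor	4
inhibitors	4
suppresses	4
suppress	4
blocks	4
block	4
blockade	4
downregulates	4
downregulate	4
down-regulates	4
attenuates	4
attenuate	4
reduces	4
reduce	4
decreases	4
represses	4
impairs	4
agonist	5
agonists	5
agonism	5
agonizes	5
antagonist	6
antagonists	6
antagonism	6
antagonizes	6
antagonize	6
blocker	6
blockers	6
substrate	9
substrates	9
metabolizes	9
metabolized	9
metabolism	9
catalyzes	9
catalyzed	9
hydrolyzes	9
caused	9
causes	9
produces	9
production	9
generates	9
synthesizes	9
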