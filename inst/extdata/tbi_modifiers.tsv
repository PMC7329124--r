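no	ABSENT	no	forward
no evidence of	ABSENT	no\s+evidence\s+(of|for)	forward
not	ABSENT	not	forward
without	ABSENT	without	forward
without evidence of	ABSENT	without\s+evidence\s+(of|for)	forward
negative for	ABSENT	negative\s+for	forward
is negative	ABSENT	(is|are|was|were)\s+negative	backward
not seen	ABSENT	not\s+(seen|identified|visualized|appreciated)	backward
is absent	ABSENT	(is|are)\s+absent	backward
do not appear significantly changed	PRESENT	do(es)?\s+not\s+appear\s+(significantly\s+)?changed	bidirectional
there is	PRESENT	there\s+(is|are)	forward
is present	PRESENT	(is|are)\s+present	backward
is seen	PRESENT	(is|are)\s+(seen|noted|identified|visualized|demonstrated|evident)	backward
demonstrates	PRESENT	demonstrat(es|ing)	forward
consistent with	PRESENT	(consistent|compatible)\s+with	forward
multifocal	PRESENT	multifocal	forward
in the	PRESENT	in\s+the	backward
possible	SUSPECTED	possib(le|ly)	forward
probable	SUSPECTED	probab(le|ly)	forward
suspicious for	SUSPECTED	(suspicious|concerning)\s+for	forward
may represent	SUSPECTED	may\s+(represent|reflect|indicate)	forward
suspected	SUSPECTED	(is\s+|are\s+)?suspected	backward
was not excluded	INDETERMINATE	(was|were)\snot\sexcluded	backward
cannot be excluded	INDETERMINATE	can\s?not\s+be\s+(excluded|ruled\s+out)	backward
differential includes	INDETERMINATE	differential\s+(diagnosis\s+)?includes	forward
versus	INDETERMINATE	versus	bidirectional
is normal	NORMAL	(is|are)\s+(normal|unremarkable|preserved|patent|intact|within\s+normal\s+limits)	backward
normal	NORMAL	normal	forward
effacement of	ABNORMAL	effacement\s+of	forward
is effaced	ABNORMAL	(is|are)\s+effaced	backward
loss of	ABNORMAL	loss\s+of	forward
blurring of	ABNORMAL	blurring\s+of	forward
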