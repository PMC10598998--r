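[QUESTION_1] In the last 7 days, have you had any cold or flu symptoms?
(1) No -> END
(2) Yes

[QUESTION_2] Which symptoms have you had? Select all that apply.
[13] runny nose -> DECON1
[14] headache -> ACHE1
[15] fever -> TEMP
< -> END>

[DECON1] Did you take a decongestant for your runny nose?
(1) Yes -> DECON2
(0) No

[DECON2] Which decongestant did you take?
|__|

[ACHE1] How severe was your headache?
(1) mild
(2) moderate
(3) severe

[TEMP] What was your highest temperature, in degrees Fahrenheit?
|__|__| min=90 max=120

[END] Thank you for completing this questionnaire.
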