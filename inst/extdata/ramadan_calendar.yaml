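# Gregorian dates of the Ramadan month, 2013-2019 (observed calendar used
# in the Netherlands). Supply your own file for other years or conventions.
2013: {start: 2013-07-09, end: 2013-08-07}
2014: {start: 2014-06-28, end: 2014-07-27}
2015: {start: 2015-06-18, end: 2015-07-16}
2016: {start: 2016-06-06, end: 2016-07-05}
2017: {start: 2017-05-27, end: 2017-06-24}
2018: {start: 2018-05-16, end: 2018-06-14}
2019: {start: 2019-05-06, end: 2019-06-03}
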